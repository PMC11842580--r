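# CDI decision table: (column, previous class, sub-condition) -> class at T.
# Columns encode the exceedance flags (spi, sma, fapar) at time T:
#   A=(0,0,0) B=(1,0,0) C=(0,1,0) D=(0,0,1) E=(0,1,1) F=(1,1,0) G=(1,0,1) H=(1,1,1)
# where spi = (SPI-1 < -2) OR (SPI-3 < -1), sma = (SMA <= -1), fapar = (FAPAR anomaly <= -1).
# cond is one of: any, wet_spi, not_wet_spi, sma_partial, not_sma_partial,
# fapar_partial, not_fapar_partial; wet_spi = (SPI-1 > 0.5) AND (SPI-3 > 0),
# *_partial = anomaly in (-0.5, 0]. For each (column, prev) the conditions
# must partition: either a single "any" row or a complementary pair.
# The engine treats this file as data; edits here change the framework
# without touching code.
column,prev,cond,out
A,NO_DROUGHT,any,NO_DROUGHT
A,WATCH,any,RECOVERY
A,WARNING,sma_partial,TEMP_SM_RECOVERY
A,WARNING,not_sma_partial,RECOVERY
A,ALERT,fapar_partial,TEMP_VEG_RECOVERY
A,ALERT,not_fapar_partial,RECOVERY
A,RECOVERY,any,NO_DROUGHT
A,TEMP_SM_RECOVERY,sma_partial,TEMP_SM_RECOVERY
A,TEMP_SM_RECOVERY,not_sma_partial,NO_DROUGHT
A,TEMP_VEG_RECOVERY,fapar_partial,TEMP_VEG_RECOVERY
A,TEMP_VEG_RECOVERY,not_fapar_partial,NO_DROUGHT
B,NO_DROUGHT,any,WATCH
B,WATCH,any,WATCH
B,WARNING,any,WATCH
B,ALERT,any,WATCH
B,RECOVERY,any,WATCH
B,TEMP_SM_RECOVERY,any,WATCH
B,TEMP_VEG_RECOVERY,any,WATCH
C,NO_DROUGHT,wet_spi,NO_DROUGHT
C,NO_DROUGHT,not_wet_spi,WARNING
C,WATCH,any,WARNING
C,WARNING,any,WARNING
C,ALERT,any,WARNING
C,RECOVERY,wet_spi,NO_DROUGHT
C,RECOVERY,not_wet_spi,WARNING
C,TEMP_SM_RECOVERY,any,WARNING
C,TEMP_VEG_RECOVERY,any,WARNING
D,NO_DROUGHT,any,NO_DROUGHT
D,WATCH,any,ALERT
D,WARNING,any,ALERT
D,ALERT,any,ALERT
D,RECOVERY,any,ALERT
D,TEMP_SM_RECOVERY,any,ALERT
D,TEMP_VEG_RECOVERY,any,ALERT
E,NO_DROUGHT,any,ALERT
E,WATCH,any,ALERT
E,WARNING,any,ALERT
E,ALERT,any,ALERT
E,RECOVERY,any,ALERT
E,TEMP_SM_RECOVERY,any,ALERT
E,TEMP_VEG_RECOVERY,any,ALERT
F,NO_DROUGHT,any,WARNING
F,WATCH,any,WARNING
F,WARNING,any,WARNING
F,ALERT,any,WARNING
F,RECOVERY,any,WARNING
F,TEMP_SM_RECOVERY,any,WARNING
F,TEMP_VEG_RECOVERY,any,WARNING
G,NO_DROUGHT,any,ALERT
G,WATCH,any,ALERT
G,WARNING,any,ALERT
G,ALERT,any,ALERT
G,RECOVERY,any,ALERT
G,TEMP_SM_RECOVERY,any,ALERT
G,TEMP_VEG_RECOVERY,any,ALERT
H,NO_DROUGHT,any,ALERT
H,WATCH,any,ALERT
H,WARNING,any,ALERT
H,ALERT,any,ALERT
H,RECOVERY,any,ALERT
H,TEMP_SM_RECOVERY,any,ALERT
H,TEMP_VEG_RECOVERY,any,ALERT
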