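pollutant,averaging_period,standard,units
CO,8 hours,9.0,ppm
NO2,1 hour,0.12,ppm
O3_1h,1 hour,0.10,ppm
O3_4h,4 hours,0.08,ppm
SO2,1 hour,0.20,ppm
PM10,1 day,50,ug/m3
PM2.5,1 day,25,ug/m3
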