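maritime:
  monthly_tmin_mean:
  - 2.0
  - 2.0
  - 4.0
  - 6.0
  - 9.0
  - 12.0
  - 14.0
  - 14.0
  - 12.0
  - 9.0
  - 5.0
  - 3.0
  monthly_tmax_mean:
  - 8.0
  - 9.0
  - 12.0
  - 16.0
  - 19.0
  - 22.0
  - 24.0
  - 24.0
  - 21.0
  - 16.0
  - 11.0
  - 9.0
  monthly_precip_mean:
  - 70.0
  - 55.0
  - 55.0
  - 50.0
  - 55.0
  - 55.0
  - 60.0
  - 65.0
  - 60.0
  - 75.0
  - 75.0
  - 75.0
  precip_wet_day_prob: 0.45
  srad_annual_peak: 20.0
  interannual_sd: 0.8
continental:
  monthly_tmin_mean:
  - -6.0
  - -5.0
  - -1.0
  - 4.0
  - 9.0
  - 13.0
  - 16.0
  - 15.0
  - 10.0
  - 4.0
  - 0.0
  - -4.0
  monthly_tmax_mean:
  - 0.0
  - 2.0
  - 8.0
  - 15.0
  - 21.0
  - 26.0
  - 28.0
  - 27.0
  - 21.0
  - 13.0
  - 6.0
  - 1.0
  monthly_precip_mean:
  - 35.0
  - 30.0
  - 35.0
  - 40.0
  - 55.0
  - 70.0
  - 75.0
  - 65.0
  - 45.0
  - 40.0
  - 40.0
  - 40.0
  precip_wet_day_prob: 0.35
  srad_annual_peak: 23.0
  interannual_sd: 1.2
mediterranean:
  monthly_tmin_mean:
  - 3.0
  - 3.0
  - 5.0
  - 8.0
  - 12.0
  - 16.0
  - 18.0
  - 18.0
  - 15.0
  - 11.0
  - 7.0
  - 4.0
  monthly_tmax_mean:
  - 11.0
  - 12.0
  - 15.0
  - 18.0
  - 23.0
  - 28.0
  - 31.0
  - 31.0
  - 26.0
  - 20.0
  - 15.0
  - 12.0
  monthly_precip_mean:
  - 55.0
  - 45.0
  - 45.0
  - 45.0
  - 35.0
  - 20.0
  - 10.0
  - 15.0
  - 40.0
  - 65.0
  - 70.0
  - 60.0
  precip_wet_day_prob: 0.28
  srad_annual_peak: 26.0
  interannual_sd: 1.0
subarctic:
  monthly_tmin_mean:
  - -14.0
  - -13.0
  - -9.0
  - -3.0
  - 2.0
  - 7.0
  - 9.0
  - 8.0
  - 4.0
  - -1.0
  - -7.0
  - -12.0
  monthly_tmax_mean:
  - -7.0
  - -6.0
  - -1.0
  - 4.0
  - 9.0
  - 13.0
  - 14.5
  - 13.0
  - 8.0
  - 2.0
  - -3.0
  - -6.0
  monthly_precip_mean:
  - 30.0
  - 25.0
  - 25.0
  - 30.0
  - 40.0
  - 50.0
  - 60.0
  - 55.0
  - 50.0
  - 45.0
  - 40.0
  - 35.0
  precip_wet_day_prob: 0.4
  srad_annual_peak: 20.0
  interannual_sd: 1.5
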