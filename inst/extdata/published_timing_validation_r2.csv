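dataset,n_years,full_r2,forecast_r2,validation_r2
humpback_arrival,24,0.662,0.458,0.471
humpback_departure,24,0.681,0.681,0.588
blue_arrival,23,0.770,0.263,0.574
gray_north_departure,23,0.701,0.290,0.579
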