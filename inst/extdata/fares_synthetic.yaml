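# SYNTHETIC fare schedule (EUR). The official patient-travel reimbursement
# tariffs behind the study are not publicly printed; these unit fares are
# calibration artifacts, solved (scratch once, then frozen) so that the
# default synthetic cohort's expected per-consultation travel cost equals
# the published EUR 148.65 (standard) / 40.73 (telemedicine) and, with the
# wage below, travel+time equals EUR 182.50 / 51.77. They are NOT the
# Norwegian Patient Travel Agency's actual rates.
modes:
  taxi:         {per_trip: 5.00, per_km: 0}
  bus:          {per_trip: 0, per_km: 0.70}
  private_car:  {per_trip: 0, per_km: 0.0505}
  express_boat: {per_trip: 0, per_km: 0.9127}
  ferry:        {per_trip: 0, per_km: 0}
  airplane:     {per_trip: 0, per_km: 1.20}
  other:        {per_trip: 0, per_km: 0}
companion_multiplier: 0.5
ferry_surcharge: 10.0
extra_transport_fee: 6.0
user_fee: 31.04
average_hourly_wage: 20.3033
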