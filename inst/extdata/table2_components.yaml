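# Service cost configuration for the teleorthopedic outpatient clinic.
# Amounts in EUR (converted from NOK at the fixed study exchange rate before
# this file was written; conversion never happens downstream).
# Categories: investment (annuitized), recurring_annual, per_consultation
# (EUR per consultation, scales linearly with yearly volume).
# Alternatives: telemedicine_A = dedicated videoconferencing units,
# telemedicine_B = Skype-for-Business setup, shared = counts toward both
# telemedicine alternatives, standard = hospital outpatient care.
currency: EUR
nok_per_eur: 9.60
annuity:
  discount_rate: 0.03
  lifetime_years: 5
reference_volume: 300
components:
  # --- alternative A: dedicated videoconferencing units -------------------
  - {name: videoconferencing_unit_hospital, amount: 5104, category: investment,
     site: hospital, alternative: telemedicine_A, payer: health_sector}
  - {name: videoconferencing_unit_remote, amount: 6250, category: investment,
     site: remote_center, alternative: telemedicine_A, payer: health_sector}
  - {name: extra_screen_remote, amount: 156, category: investment,
     site: remote_center, alternative: telemedicine_A, payer: health_sector}
  - {name: line_rental_health_net, amount: 1250, category: recurring_annual,
     site: remote_center, alternative: telemedicine_A, payer: health_sector}
  # --- alternative B: Skype-for-Business setup (no dedicated line rent) ---
  - {name: web_camera_hospital, amount: 96, category: investment,
     site: hospital, alternative: telemedicine_B, payer: health_sector}
  - {name: camera_microphone_remote, amount: 937, category: investment,
     site: remote_center, alternative: telemedicine_B, payer: health_sector}
  - {name: signage_screens_remote, amount: 1666, category: investment,
     site: remote_center, alternative: telemedicine_B, payer: health_sector}
  - {name: table_microphone_hospital, amount: 111, category: investment,
     site: hospital, alternative: telemedicine_B, payer: health_sector}
  # --- shared between both telemedicine alternatives ----------------------
  - {name: personal_computer_remote, amount: 463, category: investment,
     site: remote_center, alternative: shared, payer: health_sector}
  - {name: printer_remote, amount: 114, category: investment,
     site: remote_center, alternative: shared, payer: health_sector}
  - {name: initial_training_nurse_physician, amount: 4424, category: investment,
     site: remote_center, alternative: shared, payer: health_sector}
  - {name: technical_support, amount: 0, category: recurring_annual,
     site: hospital, alternative: shared, payer: health_sector}
  - {name: room_rent_remote, amount: 3542, category: recurring_annual,
     site: remote_center, alternative: shared, payer: health_sector}
  - {name: nurse_remote_20pct, amount: 12083, category: recurring_annual,
     site: remote_center, alternative: shared, payer: health_sector}
  # 5 of 300 yearly telemedicine consultations need a repeat hospital visit:
  # 204 EUR/year at the 300 reference volume = 0.68 EUR per consultation.
  - {name: second_consultation_hospital, amount: 0.68,
     category: per_consultation, site: hospital, alternative: shared,
     payer: health_sector}
  # --- standard care ------------------------------------------------------
  # Nurse assists in 32% of standard consultations (~25 h per 300
  # consultations, 906 EUR/year at the reference volume = 3.02 EUR each).
  - {name: nurse_assistance_standard, amount: 3.02,
     category: per_consultation, site: hospital, alternative: standard,
     payer: health_sector}
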