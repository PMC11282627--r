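surveys:
  SVY_A:
    place:
      '11': home
      '21': lower
      '22': hospital
      '26': private_clinic
    attendant:
      '1': skilled
      '2': unskilled
    stay_units:
      hrs: hours
      day: days
    pnc_units:
      hrs: hours
      day: days
      none: none
  SVY_B:
    place:
      '11': home
      '21': lower
      '22': hospital
      '26': private_hospital
    attendant:
      '1': skilled
      '2': unskilled
    stay_units:
      hrs: hours
      day: days
    pnc_units:
      hrs: hours
      day: days
      none: none
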