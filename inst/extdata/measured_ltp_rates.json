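{
  "_comment": "LTP dose rates measured with two traditional dosimeters at 8 kV, 1 kHz, 2 slm; consumed as configured comparison constants only.",
  "fricke":  {"rate_Gy_per_s": 0.76, "method": "Fricke (ferrous-ferric) chemical dosimeter"},
  "alanine": {"rate_Gy_per_s": 0.01, "method": "alanine pellet read by EPR spectroscopy"}
}
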