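#!ndf
# Squid-axon sodium and potassium channel prototypes (6.3 C), SI units,
# resting potential -0.070 V. GATE <name> <power> <alpha> <beta>, each rate
# as <form A offset scale> with absolute voltage offsets.
CHANNEL /na
  PARAMETER GBAR 1200
  PARAMETER EREV 0.045
  GATE m 3 linoid 100000 -0.045 0.01 exponential 4000 -0.07 0.018
  GATE h 1 exponential 70 -0.07 0.02 sigmoid 1000 -0.04 0.01
END
CHANNEL /k
  PARAMETER GBAR 360
  PARAMETER EREV -0.082
  GATE n 4 linoid 10000 -0.06 0.01 exponential 125 -0.07 0.08
END
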