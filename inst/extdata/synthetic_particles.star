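# Synthetic example particle table (not experimental data): myosin head
# candidate coordinates in pixel units, for readStarParticles().
data_particles

loop_
_rlnCoordinateX #1
_rlnCoordinateY #2
_rlnCoordinateZ #3
_rlnAngleRot #4
142.05 40.62 73.88 12.5
139.80 56.49 76.02 -48.0
260.33 41.11 131.70 101.2
258.14 57.01 129.55 7.9
381.71 40.80 187.43 -120.4
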