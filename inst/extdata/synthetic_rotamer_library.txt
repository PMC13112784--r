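# SYNTHETIC rotamer library fragment in the backbone-dependent (bbdep)
# text layout: residue, phi, psi, count, r1-r4, probability, chi1-4
# means, chi1-4 sigmas.  Values are illustrative only (constructed for
# examples and documentation, not taken from any published library).
ARG  -180 -180  84  1 1 1 1  0.60   62.5  176.9  176.7   85.7  6.9 8.2 10.2 10.1
ARG  -180 -180  40  2 1 1 1  0.30 -177.2  175.1  178.4   88.3  7.1 8.0  9.8 10.3
ARG  -180 -180  12  3 1 1 1  0.10  -65.2  180.0  177.5   87.0  7.5 8.4 10.0 10.4
LEU  -60  -40  120  1 1 0 0  0.70  -64.9  176.0    0.0    0.0  6.5 7.9  0.0  0.0
LEU  -60  -40   40  2 1 0 0  0.20 -176.4   63.1    0.0    0.0  7.0 8.1  0.0  0.0
LEU  -60  -40   15  3 2 0 0  0.10   62.8  -68.9    0.0    0.0  7.4 8.6  0.0  0.0
SER  -60  -40   90  1 0 0 0  0.55   64.7    0.0    0.0    0.0  6.8 0.0  0.0  0.0
SER  -60  -40   60  2 0 0 0  0.35  -69.1    0.0    0.0    0.0  7.0 0.0  0.0  0.0
SER  -60  -40   20  3 0 0 0  0.10  178.3    0.0    0.0    0.0  7.2 0.0  0.0  0.0
TYR  -120  140  75  1 1 0 0  0.50  -66.2   94.8    0.0    0.0  7.1 9.3  0.0  0.0
TYR  -120  140  45  2 1 0 0  0.30  177.5   77.7    0.0    0.0  7.3 9.0  0.0  0.0
TYR  -120  140  25  3 1 0 0  0.20   62.4   90.1    0.0    0.0  7.6 9.2  0.0  0.0
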