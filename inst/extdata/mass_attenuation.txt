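# Mass attenuation coefficients mu/rho in cm^2/g, 10-120 keV.
# Values are transcriptions (with log-log interpolation onto the 10 keV
# grid) of the public NIST XCOM photon cross-section database for liquid
# water, cortical bone (ICRU-44), elemental gold (K edge 80.7 keV) and
# iron (as stainless steel).
energy_keV water bone gold steel
10  5.329  28.51  95.0  170.6
20  0.8096  4.001  78.8   25.68
30  0.3756  1.331  32.0    8.176
40  0.2683  0.6655 14.4    3.629
50  0.2269  0.4242  7.80   1.958
60  0.2059  0.3148  4.53   1.205
70  0.1931  0.2615  2.99   0.832
80  0.1837  0.2229  2.21   0.5952
90  0.1766  0.2028  6.47   0.470
100 0.1707  0.1855  5.16   0.3717
110 0.1658  0.1740  4.25   0.337
120 0.1614  0.1680  3.56   0.308
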