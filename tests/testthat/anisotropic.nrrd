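NRRD0004
# small anisotropic test grid, ascii encoding
type: double
dimension: 3
space dimension: 3
sizes: 2 3 4
space directions: (1,0,0) (0,1,0) (0,0,2.5)
space origin: (-0.5,1.5,10)
kinds: domain domain domain
encoding: ascii

1 2
3 4
5 6

7 8
9 10
11 12

13 14
15 16
17 18

19 20
21 22
23 24
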