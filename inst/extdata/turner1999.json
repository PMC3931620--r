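{
 "name": "turner1999",
 "reference_temperature": 310.15,
 "pair_order": [
  "AU",
  "UA",
  "GC",
  "CG",
  "GU",
  "UG"
 ],
 "stack": {
  "dG37": [
   [
    -0.9,
    -1.1,
    -2.1,
    -2.2,
    -0.6,
    -1.4
   ],
   [
    -1.3,
    -0.9,
    -2.1,
    -2.4,
    -1.0,
    -1.3
   ],
   [
    -2.4,
    -2.2,
    -3.3,
    -3.4,
    -1.5,
    -2.5
   ],
   [
    -2.1,
    -2.1,
    -2.4,
    -3.3,
    -1.4,
    -2.1
   ],
   [
    -1.3,
    -1.4,
    -2.1,
    -2.5,
    -0.5,
    1.3
   ],
   [
    -1.0,
    -0.6,
    -1.4,
    -1.5,
    0.3,
    -0.5
   ]
  ],
  "dH": [
   [
    -6.8,
    -9.4,
    -10.5,
    -11.4,
    -3.2,
    -8.8
   ],
   [
    -7.7,
    -6.8,
    -10.4,
    -12.4,
    -7.0,
    -12.8
   ],
   [
    -12.4,
    -11.4,
    -13.4,
    -14.9,
    -8.3,
    -12.6
   ],
   [
    -10.4,
    -10.5,
    -10.6,
    -13.4,
    -5.6,
    -12.1
   ],
   [
    -12.8,
    -8.8,
    -12.1,
    -12.6,
    -13.5,
    -14.6
   ],
   [
    -7.0,
    -3.2,
    -5.6,
    -8.3,
    -9.3,
    -13.5
   ]
  ]
 },
 "hairpin": {
  "dG37": [
   null,
   null,
   5.7,
   5.6,
   5.6,
   5.4,
   5.9,
   5.6,
   6.4,
   6.5,
   6.6,
   6.7,
   6.78,
   6.86,
   6.94,
   7.01,
   7.07,
   7.13,
   7.19,
   7.25,
   7.3,
   7.35,
   7.4,
   7.44,
   7.49,
   7.53,
   7.57,
   7.61,
   7.65,
   7.69
  ],
  "dH": [
   null,
   null,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0
  ]
 },
 "bulge": {
  "dG37": [
   3.8,
   2.8,
   3.2,
   3.6,
   4.0,
   4.4,
   4.59,
   4.7,
   4.8,
   4.9,
   5.0,
   5.1,
   5.19,
   5.27,
   5.34,
   5.41,
   5.48,
   5.54,
   5.6,
   5.65,
   5.71,
   5.76,
   5.8,
   5.85,
   5.89,
   5.94,
   5.98,
   6.02,
   6.05,
   6.09
  ],
  "dH": [
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0
  ]
 },
 "internal": {
  "dG37": [
   null,
   4.1,
   5.1,
   1.7,
   1.8,
   2.0,
   2.2,
   2.3,
   2.4,
   2.5,
   2.6,
   2.7,
   2.78,
   2.86,
   2.94,
   3.01,
   3.07,
   3.13,
   3.19,
   3.25,
   3.3,
   3.35,
   3.4,
   3.45,
   3.49,
   3.53,
   3.57,
   3.61,
   3.65,
   3.69
  ],
  "dH": [
   null,
   null,
   null,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0,
   0.0
  ]
 },
 "multiloop": {
  "a": 3.4,
  "a_dH": 0.0,
  "b": 0.4,
  "b_dH": 0.0,
  "c": 0.0,
  "c_dH": 0.0
 },
 "terminal_nongc": {
  "dG37": 0.5,
  "dH": 0.0
 },
 "lxc": 1.07856,
 "tetraloop": {
  "dG37": {
   "GGGGAC": 0.2,
   "GGUGAC": 0.2,
   "CGAAAG": 0.4,
   "GGAGAC": 0.2,
   "CGCAAG": 0.4,
   "GGAAAC": 0.2,
   "CGGAAG": 0.4,
   "CUUCGG": 0.8,
   "CGUGAG": 0.4,
   "CGAAGG": 1.5,
   "CUACGG": 1.3,
   "GGCAAC": 0.7,
   "CGCGAG": 0.9,
   "UGAGAG": 2.3,
   "CGAGAG": 1.4,
   "AGAAAU": 2.5,
   "CGUAAG": 1.4,
   "CUAACG": 2.2,
   "UGAAAG": 2.8,
   "GGAAGC": 2.7,
   "GGGAAC": 1.7,
   "UGAAAA": 2.7,
   "AGCAAU": 3.0,
   "AGUAAU": 3.0,
   "CGGGAG": 1.9,
   "AGUGAU": 3.0,
   "GGCGAC": 1.7,
   "GGGAGC": 2.7,
   "GUGAAC": 2.2,
   "UGGAAA": 2.7
  },
  "dH": {
   "GGGGAC": -11.1,
   "GGUGAC": -11.1,
   "CGAAAG": -13.4,
   "GGAGAC": -11.1,
   "CGCAAG": -13.4,
   "GGAAAC": -11.1,
   "CGGAAG": -13.4,
   "CUUCGG": -12.1,
   "CGUGAG": -13.4,
   "CGAAGG": -13.4,
   "CUACGG": -12.1,
   "GGCAAC": -11.1,
   "CGCGAG": -13.4,
   "UGAGAG": -10.6,
   "CGAGAG": -13.4,
   "AGAAAU": -7.4,
   "CGUAAG": -13.4,
   "CUAACG": -11.4,
   "UGAAAG": -10.6,
   "GGAAGC": -10.2,
   "GGGAAC": -11.1,
   "UGAAAA": -7.8,
   "AGCAAU": -7.4,
   "AGUAAU": -7.4,
   "CGGGAG": -13.4,
   "AGUGAU": -7.4,
   "GGCGAC": -11.1,
   "GGGAGC": -10.2,
   "GUGAAC": -9.0,
   "UGGAAA": -7.8
  }
 }
}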