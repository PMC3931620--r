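{
 "name": "turner2004",
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
   5.4,
   5.6,
   5.7,
   5.4,
   6.0,
   5.5,
   6.4,
   6.5,
   6.6,
   6.7,
   6.8,
   6.9,
   6.9,
   7.0,
   7.1,
   7.1,
   7.2,
   7.2,
   7.3,
   7.3,
   7.4,
   7.4,
   7.5,
   7.5,
   7.5,
   7.6,
   7.6,
   7.7
  ],
  "dH": [
   null,
   null,
   1.3,
   4.8,
   3.6,
   -2.9,
   1.3,
   -2.9,
   5.0,
   5.0,
   5.0,
   5.0,
   5.0,
   5.0,
   5.0,
   5.0,
   5.0,
   5.0,
   5.0,
   5.0,
   5.0,
   5.0,
   5.0,
   5.0,
   5.0,
   5.0,
   5.0,
   5.0,
   5.0,
   5.0
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
   4.6,
   4.7,
   4.8,
   4.9,
   5.0,
   5.1,
   5.2,
   5.3,
   5.4,
   5.4,
   5.5,
   5.5,
   5.6,
   5.7,
   5.7,
   5.8,
   5.8,
   5.8,
   5.9,
   5.9,
   6.0,
   6.0,
   6.0,
   6.1
  ],
  "dH": [
   10.6,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1,
   7.1
  ]
 },
 "internal": {
  "dG37": [
   null,
   1.0,
   1.0,
   1.1,
   2.0,
   2.0,
   2.1,
   2.3,
   2.4,
   2.5,
   2.6,
   2.7,
   2.8,
   2.9,
   2.9,
   3.0,
   3.1,
   3.1,
   3.2,
   3.3,
   3.3,
   3.4,
   3.4,
   3.5,
   3.5,
   3.5,
   3.6,
   3.6,
   3.7,
   3.7
  ],
  "dH": [
   null,
   -7.2,
   -7.2,
   -7.2,
   -6.8,
   -1.3,
   -1.3,
   -1.3,
   -1.3,
   -1.3,
   -1.3,
   -1.3,
   -1.3,
   -1.3,
   -1.3,
   -1.3,
   -1.3,
   -1.3,
   -1.3,
   -1.3,
   -1.3,
   -1.3,
   -1.3,
   -1.3,
   -1.3,
   -1.3,
   -1.3,
   -1.3,
   -1.3,
   -1.3
  ]
 },
 "multiloop": {
  "a": 9.3,
  "a_dH": 30.0,
  "b": -0.9,
  "b_dH": -2.2,
  "c": 0.0,
  "c_dH": 0.0
 },
 "terminal_nongc": {
  "dG37": 0.5,
  "dH": 3.7
 },
 "lxc": 1.07856,
 "tetraloop": {
  "dG37": {
   "CAACGG": 5.5,
   "CCAAGG": 3.3,
   "CCACGG": 3.7,
   "CCCAGG": 3.4,
   "CCGAGG": 3.5,
   "CCGCGG": 3.6,
   "CCUAGG": 3.7,
   "CCUCGG": 2.5,
   "CUAAGG": 3.6,
   "CUACGG": 2.8,
   "CUCAGG": 3.7,
   "CUCCGG": 2.7,
   "CUGCGG": 2.8,
   "CUUAGG": 3.5,
   "CUUCGG": 3.7,
   "CUUUGG": 3.7
  },
  "dH": {
   "CAACGG": 6.9,
   "CCAAGG": -10.3,
   "CCACGG": -3.3,
   "CCCAGG": -8.9,
   "CCGAGG": -6.6,
   "CCGCGG": -7.5,
   "CCUAGG": -3.5,
   "CCUCGG": -13.9,
   "CUAAGG": -7.6,
   "CUACGG": -10.7,
   "CUCAGG": -6.6,
   "CUCCGG": -12.9,
   "CUGCGG": -10.7,
   "CUUAGG": -6.2,
   "CUUCGG": -15.3,
   "CUUUGG": -6.8
  }
 }
}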