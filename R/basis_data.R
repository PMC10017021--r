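# Built-in Gaussian basis sets (standard Basis Set Exchange parameters).
# Each element entry is a list of shells: l quantum number, primitive
# exponents (bohr^-2) and contraction coefficients over normalized
# primitives. Spherical (5d) convention for l = 2.

.basis_library <- list(
  `sto-3g` = list(
    `H` = list(
      list(l = 0, exp = c(3.42525091, 0.62391373, 0.1688554), coef = c(0.15432897, 0.53532814, 0.44463454))
    ),
    `He` = list(
      list(l = 0, exp = c(6.36242139, 1.158923, 0.31364979), coef = c(0.15432897, 0.53532814, 0.44463454))
    ),
    `C` = list(
      list(l = 0, exp = c(71.616837, 13.045096, 3.5305122), coef = c(0.15432897, 0.53532814, 0.44463454)),
      list(l = 0, exp = c(2.9412494, 0.6834831, 0.2222899), coef = c(-0.09996723, 0.39951283, 0.70011547)),
      list(l = 1, exp = c(2.9412494, 0.6834831, 0.2222899), coef = c(0.15591627, 0.60768372, 0.39195739))
    ),
    `N` = list(
      list(l = 0, exp = c(99.106169, 18.052312, 4.8856602), coef = c(0.15432897, 0.53532814, 0.44463454)),
      list(l = 0, exp = c(3.7804559, 0.8784966, 0.2857144), coef = c(-0.09996723, 0.39951283, 0.70011547)),
      list(l = 1, exp = c(3.7804559, 0.8784966, 0.2857144), coef = c(0.15591627, 0.60768372, 0.39195739))
    ),
    `O` = list(
      list(l = 0, exp = c(130.70932, 23.808861, 6.4436083), coef = c(0.15432897, 0.53532814, 0.44463454)),
      list(l = 0, exp = c(5.0331513, 1.1695961, 0.380389), coef = c(-0.09996723, 0.39951283, 0.70011547)),
      list(l = 1, exp = c(5.0331513, 1.1695961, 0.380389), coef = c(0.15591627, 0.60768372, 0.39195739))
    )
  ),
  `cc-pvdz` = list(
    `H` = list(
      list(l = 0, exp = c(13.01, 1.962, 0.4446), coef = c(0.019685, 0.137977, 0.478148)),
      list(l = 0, exp = c(0.122), coef = c(1.0)),
      list(l = 1, exp = c(0.727), coef = c(1.0))
    ),
    `C` = list(
      list(l = 0, exp = c(6665.0, 1000.0, 228.0, 64.71, 21.06, 7.495, 2.797, 0.5215), coef = c(0.000692, 0.005329, 0.027077, 0.101718, 0.27474, 0.448564, 0.285074, 0.015204)),
      list(l = 0, exp = c(6665.0, 1000.0, 228.0, 64.71, 21.06, 7.495, 2.797, 0.5215), coef = c(-0.000146, -0.001154, -0.005725, -0.023312, -0.063955, -0.149981, -0.127262, 0.544529)),
      list(l = 0, exp = c(0.1596), coef = c(1.0)),
      list(l = 1, exp = c(9.439, 2.002, 0.5456), coef = c(0.038109, 0.20948, 0.508557)),
      list(l = 1, exp = c(0.1517), coef = c(1.0)),
      list(l = 2, exp = c(0.55), coef = c(1.0))
    ),
    `N` = list(
      list(l = 0, exp = c(9046.0, 1357.0, 309.3, 87.73, 28.56, 10.21, 3.838, 0.7466), coef = c(0.0007, 0.005389, 0.027406, 0.103207, 0.278723, 0.44854, 0.278238, 0.01544)),
      list(l = 0, exp = c(9046.0, 1357.0, 309.3, 87.73, 28.56, 10.21, 3.838, 0.7466), coef = c(-0.000153, -0.001208, -0.005992, -0.024544, -0.067459, -0.158078, -0.121831, 0.549003)),
      list(l = 0, exp = c(0.2248), coef = c(1.0)),
      list(l = 1, exp = c(13.55, 2.917, 0.7973), coef = c(0.039919, 0.217169, 0.510319)),
      list(l = 1, exp = c(0.2185), coef = c(1.0)),
      list(l = 2, exp = c(0.817), coef = c(1.0))
    ),
    `O` = list(
      list(l = 0, exp = c(11720.0, 1759.0, 400.8, 113.7, 37.03, 13.27, 5.025, 1.013), coef = c(0.00071, 0.00547, 0.027837, 0.1048, 0.283062, 0.448719, 0.270952, 0.015458)),
      list(l = 0, exp = c(11720.0, 1759.0, 400.8, 113.7, 37.03, 13.27, 5.025, 1.013), coef = c(-0.00016, -0.001263, -0.006267, -0.025716, -0.070924, -0.165411, -0.116955, 0.557368)),
      list(l = 0, exp = c(0.3023), coef = c(1.0)),
      list(l = 1, exp = c(17.7, 3.854, 1.046), coef = c(0.043018, 0.228913, 0.508728)),
      list(l = 1, exp = c(0.2753), coef = c(1.0)),
      list(l = 2, exp = c(1.185), coef = c(1.0))
    )
  )
)
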