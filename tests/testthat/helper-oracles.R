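# Frozen high-precision reference values and small brute-force oracles used
# across the suite.

# Mittag-Leffler E_alpha(-x) reference grid, computed once with 60-digit
# arithmetic by two independent routes (extended-precision power series for
# x <= 2, extended-precision quadrature of the spectral representation for
# larger x; the routes agree to < 1e-10 where both apply).
ml_reference <- function() {
  tab <- expand.grid(
    alpha = c(0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0),
    x = c(0, 0.1, 0.5, 1, 2, 5, 10, 20, 35, 50))
  tab <- tab[order(tab$alpha, tab$x), ]
  tab$value <- c(
    # alpha = 0.3
    1.0, 0.898811536502722547, 0.632649005943599006, 0.456594408329690644,
    0.290232226153898736, 0.137080869020270639, 0.0726497290727720861,
    0.037406226213884453, 0.0216454891900046291, 0.0152282015018146952,
    # alpha = 0.4
    1.0, 0.897188323042222333, 0.623496403875290401, 0.44206335968522341,
    0.273535299960745268, 0.124627071103737159, 0.0648271692110446595,
    0.03301089796175726, 0.01900421347525368, 0.0133416384513949542,
    # alpha = 0.5
    1.0, 0.896456979969126637, 0.615690344192925875, 0.427583576155807004,
    0.255395676310505744, 0.110704637733068626, 0.0561409927438225859,
    0.0281743487410513193, 0.0161131309568159787, 0.0112815362653237725,
    # alpha = 0.6
    1.0, 0.896594005969009266, 0.609475821956199996, 0.41332734094310621,
    0.235571031111827318, 0.0951178464387546203, 0.046589654426804281,
    0.0229465642732583764, 0.0130166116921779086, 0.00908374477310345464,
    # alpha = 0.7
    1.0, 0.897561126931386771, 0.605147592059564262, 0.399611978115599337,
    0.213786727015298273, 0.07756935776476981, 0.0361732655423091581,
    0.01739569829160398, 0.00977208791976265648, 0.00679366567038309387,
    # alpha = 0.8
    1.0, 0.899304768214485139, 0.603023715862803709, 0.386948578618976904,
    0.189796692363705303, 0.0575953847621522443, 0.0249028197619765322,
    0.011617250451432778, 0.00645345073013951692, 0.00446777615790299226,
    # alpha = 0.9
    1.0, 0.901756942449859396, 0.603405498695860982, 0.376066021424642022,
    0.163528300016931177, 0.0344313248040984183, 0.0128206060511020999,
    0.00574950781610911258, 0.00315560794911165574, 0.00217535307685697605,
    # alpha = 1.0
    1.0, 0.904837418035959568, 0.606530659712633424, 0.367879441171442322,
    0.135335283236612692, 0.0067379469990854671, 4.53999297624848515e-5,
    2.06115362243855783e-9, 6.30511676014698939e-16, 1.92874984796391778e-22)
  tab
}

# brute-force AUC over all positive/negative pairs
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# the standard six single-voxel truths used by round-trip tests
roundtrip_truths <- function() list(
  ADC  = c(S0 = 100, ADC = 1.5e-3),
  IVIM = c(S0 = 100, f = 0.15, D = 1.0e-3, Dstar = 15e-3),
  DKI  = c(S0 = 100, D = 1.5e-3, K = 0.8),
  SEM  = c(S0 = 100, DDC = 1.5e-3, alpha = 0.8),
  FROC = c(S0 = 100, D = 1.0e-3, beta = 0.8, mu = 5e-3),
  CTRW = c(S0 = 100, D = 1.0e-3, alpha = 0.9, beta = 0.9))

rel_err <- function(est, truth) max(abs(est - truth) / abs(truth))

# tiny homogeneous phantom: every in-mask voxel carries the same truth
homogeneous_phantom <- function(model, truth, scheme, shape = c(4, 4, 3)) {
  mask <- array(FALSE, shape); mask[2:3, 2:3, 2] <- TRUE
  sig <- signal_model(model, truth, scheme)
  dwi <- array(0, c(shape, length(sig)))
  nv <- prod(shape)
  for (k in seq_along(sig)) {
    sl <- array(0, shape); sl[mask] <- sig[k]
    dwi[(k - 1L) * nv + seq_len(nv)] <- sl
  }
  list(dwi = dwi, mask = mask)
}
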