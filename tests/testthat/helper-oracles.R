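# Independent oracles used across the suite. Each one deliberately takes
# a different route than the implementation it checks.

# brute-force trapezoidal convolution of exp(-k t) with a unit-area
# Gaussian centred at mu (oracle for the analytic IRF convolution)
conv_oracle <- function(t, k, mu, fwhm, n = 40001) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  lo <- mu - 8 * s
  if (t <= lo) return(0)
  tau <- seq(lo, t, length.out = n)
  g <- exp(-(tau - mu)^2 / (2 * s^2)) / (s * sqrt(2 * pi))
  f <- exp(-k * (t - tau))
  sum((g * f)[-1] + (g * f)[-n]) / 2 * (tau[2] - tau[1])
}

# normal-equations least squares (oracle for the QR projection)
normal_eq_oracle <- function(X, D) solve(crossprod(X), crossprod(X, D))

# adaptive-quadrature ensemble average of an orientation-dependent
# integrand over p = cos(theta) in [0, 1]
quad_oracle <- function(f)
  stats::integrate(f, 0, 1, rel.tol = 1e-12, abs.tol = 1e-14)$value

# 2-D (radial second-moment) Gaussian-product width oracle for the
# pump/probe beam-ratio correction
beam_ratio_oracle <- function(R, n = 200001) {
  rr <- seq(0, 40, length.out = n)
  gauss <- function(s) exp(-rr^2 / (2 * s^2))
  w <- function(g) sqrt(sum(rr^2 * g * rr) / sum(g * rr))
  w(gauss(R) * gauss(1)) / w(gauss(1))
}

# matrix-exponential concentration oracle via scaling-and-squaring
# (independent of the package's eigendecomposition path)
expm_oracle <- function(K, c0, times) {
  t(vapply(times, function(t)
    as.vector(Matrix::expm(K * t) %*% c0), numeric(length(c0))))
}

# minimal SBML documents for the import tests
sbml_doc <- function(reactions, params = c(kf = 0.5, kr = 0.2)) {
  par_xml <- paste0(sprintf('<parameter id="%s" value="%g"/>',
                            names(params), params), collapse = "")
  paste0('<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" ',
         'version="4"><model id="m"><listOfSpecies>',
         '<species id="A" initialAmount="1"/>',
         '<species id="B" initialAmount="0"/></listOfSpecies>',
         '<listOfParameters>', par_xml, '</listOfParameters>',
         '<listOfReactions>', reactions,
         '</listOfReactions></model></sbml>')
}

sbml_reaction <- function(id, reversible, reactants, products, math) {
  paste0('<reaction id="', id, '" reversible="',
         if (reversible) "true" else "false", '">',
         '<listOfReactants>',
         paste0(sprintf('<speciesReference species="%s"/>', reactants),
                collapse = ""),
         '</listOfReactants>',
         if (length(products))
           paste0('<listOfProducts>',
                  paste0(sprintf('<speciesReference species="%s"/>',
                                 products), collapse = ""),
                  '</listOfProducts>') else "",
         '<kineticLaw>',
         '<math xmlns="http://www.w3.org/1998/Math/MathML">', math,
         '</math></kineticLaw></reaction>')
}

mass_action_math <- function(k, sp)
  sprintf("<apply><times/><ci>%s</ci><ci>%s</ci></apply>", k, sp)
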