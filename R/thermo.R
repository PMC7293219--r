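## Equilibrium model of oligo-overhang capture. K = exp(-dG0 / (R T)) on the
## molar scale; the bound:free ratio K*[Oligo] is reported both literally
## (clipped at 1 when quoted as a fraction) and in the saturating two-state
## form K*[Oligo] / (1 + K*[Oligo]).

#' Gas constant in kcal / (mol K)
#' @export
R_KCAL <- 1.987e-3

#' Construct an oligo binding model
#'
#' @param delta_g0 Standard Gibbs free energy change of duplex formation,
#'   kcal/mol (negative = favourable).
#' @param temperature_k Temperature in Kelvin (> 0).
#' @param oligo_concentration Free oligo concentration, mol/L (>= 0).
#' @param gas_constant Gas constant, kcal/(mol K).
#' @return An object of class `binding_model`.
#' @export
binding_model <- function(delta_g0, temperature_k = 298.15,
                          oligo_concentration = 1e-6,
                          gas_constant = R_KCAL) {
  stopifnot(temperature_k > 0, oligo_concentration >= 0, gas_constant > 0)
  structure(
    list(delta_g0 = delta_g0, temperature_k = temperature_k,
         oligo_concentration = oligo_concentration,
         gas_constant = gas_constant),
    class = "binding_model"
  )
}

#' Equilibrium constant of oligo binding
#'
#' `K = exp(-dG0 / (R T))`, dimensionless on the molar scale.
#'
#' @param model A [binding_model()].
#' @return Numeric K.
#' @examples
#' equilibrium_constant(binding_model(0))  # 1
#' @export
equilibrium_constant <- function(model) {
  stopifnot(inherits(model, "binding_model"))
  exp(-model$delta_g0 / (model$gas_constant * model$temperature_k))
}

#' Bound-to-free strand ratio
#'
#' `K * [Oligo]`: the ratio of oligo-bound strands to free strands at
#' equilibrium when the oligo is in large excess. Taken directly as the
#' separation efficiency in the literal reading of the equilibrium model; note
#' it exceeds 1 for strongly bound oligos.
#'
#' @param K Equilibrium constant (>= 0).
#' @param oligo_concentration Oligo concentration, mol/L (>= 0).
#' @return Numeric ratio (vectorised).
#' @export
bound_ratio <- function(K, oligo_concentration) {
  stopifnot(all(K >= 0), all(oligo_concentration >= 0))
  K * oligo_concentration
}

#' Bound fraction of strands
#'
#' Two forms are provided. `"literal_clipped"` (default) reads the
#' ratio `K*[Oligo]` directly as the separated fraction and clips it at 1.
#' `"saturating"` is the standard two-state isotherm
#' `K*[Oligo] / (1 + K*[Oligo])`, bounded in `[0, 1)`. The two agree to first
#' order when `K*[Oligo] << 1`.
#'
#' @param K Equilibrium constant.
#' @param oligo_concentration Oligo concentration, mol/L.
#' @param form `"literal_clipped"` or `"saturating"`.
#' @return Numeric fraction in `[0, 1]` (vectorised).
#' @export
bound_fraction <- function(K, oligo_concentration,
                           form = c("literal_clipped", "saturating")) {
  form <- match.arg(form)
  x <- bound_ratio(K, oligo_concentration)
  switch(form,
    literal_clipped = pmin(x, 1),
    saturating = x / (1 + x)
  )
}

## Unified nearest-neighbor parameters for DNA/DNA duplexes (dH kcal/mol,
## dS cal/(mol K)), 1 M NaCl. Stacks keyed by the top-strand dinucleotide;
## initiation split into terminal G.C and terminal A.T contributions.
NN_UNIFIED <- list(
  dH = c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
         GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
         TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0),
  dS = c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
         CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
         TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
         CC = -19.9),
  init_gc = c(dH = 0.1, dS = -2.8),
  init_at = c(dH = 2.3, dS = 4.1)
)

#' Nearest-neighbor standard free energy of a perfect duplex
#'
#' Sums dinucleotide-stack enthalpies and entropies (unified DNA/DNA
#' parameter set, 1 M NaCl) plus terminal initiation terms, and returns
#' `dG0 = dH - T * dS` at the requested temperature. The parameter table is
#' pluggable so alternative published sets can be swapped in.
#'
#' @param duplex Sequence of one strand of the perfect duplex (>= 2 nt).
#' @param temperature_k Temperature in Kelvin.
#' @param params Parameter table shaped like the packaged `NN_UNIFIED`.
#' @return dG0 in kcal/mol (negative = favourable).
#' @export
nn_delta_g <- function(duplex, temperature_k = 298.15, params = NN_UNIFIED) {
  validate_dna(duplex)
  stopifnot(length(duplex) == 1L)
  n <- nchar(duplex)
  if (n < 2L) stop("duplex must be at least 2 nt")
  stacks <- substring(duplex, 1:(n - 1L), 2:n)
  dH <- sum(params$dH[stacks])
  dS <- sum(params$dS[stacks])
  for (end_base in c(substr(duplex, 1L, 1L), substr(duplex, n, n))) {
    term <- if (end_base %in% c("G", "C")) params$init_gc else params$init_at
    dH <- dH + term[["dH"]]
    dS <- dS + term[["dS"]]
  }
  dH - temperature_k * dS / 1000
}

#' Predicted separation efficiency of an oligo at a temperature
#'
#' Convenience wrapper chaining [nn_delta_g()], [equilibrium_constant()] and
#' [bound_fraction()]: the model behind the observed trends that longer
#' access oligos and lower temperatures separate more of a file.
#'
#' @param oligo Access oligo sequence (its perfect duplex with the overhang).
#' @param temperature_c Temperature in Celsius.
#' @param oligo_concentration Oligo concentration, mol/L.
#' @param form Passed to [bound_fraction()].
#' @return List: `delta_g0`, `K`, `ratio`, `fraction_clipped`,
#'   `fraction_saturating`.
#' @export
separation_model <- function(oligo, temperature_c = 25,
                             oligo_concentration = 1e-6,
                             form = c("literal_clipped", "saturating")) {
  tk <- temperature_c + 273.15
  dg <- nn_delta_g(oligo, tk)
  K <- equilibrium_constant(binding_model(dg, tk, oligo_concentration))
  list(
    delta_g0 = dg, K = K,
    ratio = bound_ratio(K, oligo_concentration),
    fraction_clipped = bound_fraction(K, oligo_concentration,
                                      "literal_clipped"),
    fraction_saturating = bound_fraction(K, oligo_concentration, "saturating")
  )
}
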