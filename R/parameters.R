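# Parameter sets and model variants for the Shh pathway ODE model.

# Canonical parameter order used to build the numeric vector handed to the
# compiled right-hand side. Order matters; do not reorder.
.param_names <- c(
  "tr_ptc", "tr_gliFL", "tr_x", "tr_gfp",
  "tl_Ptc", "tl_GliFL", "tl_X",
  "deg_ptc", "deg_gliFL", "deg_x", "deg_gfp",
  "deg_Ptc", "deg_GliFL", "deg_GliA", "deg_GliR", "deg_X",
  "conv_GliA", "conv_GliR", "act_Ptc", "k_ShhPtc", "Km_Ptch1",
  "Pol", "K_Pol_ptc", "K_Pol_gli", "K_Pol_x", "K_Pol_gfp",
  "K_Gli_ptc", "K_Gli_x", "K_Gli_gfp", "K_X_gli",
  "c_GliA", "c_GliR", "c_X"
)

.species_names <- c(
  "ptc_mRNA", "Ptc_inactive", "Ptc_active",
  "gliFL_mRNA", "GliFL", "GliA", "GliR",
  "x_mRNA", "X", "gfp_mRNA"
)

.variant_names <- c("full", "gli_stability", "ptch1_feedback", "gli_transcription")

#' Model variants of the Shh pathway
#'
#' The pathway model comes in four wirings. `"full"` keeps every coupling
#' active. Each reduced variant disables all but one candidate adaptation
#' mechanism:
#' \describe{
#'   \item{`"gli_stability"`}{ptch1 and gli transcription are constant
#'     (basal polymerase occupancy only) and the intermediary factor X is
#'     removed; the degradation rates of the three Gli isoforms remain free,
#'     so differential Gli stability is the only adaptive mechanism.}
#'   \item{`"ptch1_feedback"`}{X is removed and gli transcription is
#'     constant; the three Gli isoform degradation rates are forced equal,
#'     leaving transcriptional Ptch1 upregulation as the only mechanism.}
#'   \item{`"gli_transcription"`}{ptch1 transcription is constant (decoupled
#'     from Gli) and Gli isoform degradation rates are forced equal; X-mediated
#'     repression of gli transcription is the only mechanism.}
#' }
#'
#' @return Character vector of the four variant names.
#' @export
model_variants <- function() .variant_names

.variant_code <- function(variant) {
  variant <- match.arg(variant, .variant_names)
  match(variant, .variant_names)
}

#' Construct a pathway parameter set
#'
#' Returns a complete named parameter set for the Shh pathway model. Defaults
#' are the published reference set used for the NIH3T3 pulse simulation; any
#' parameter can be overridden by name. Reporter-gene (gfp) regulatory
#' parameters default to the ptch1 promoter values (`tr_gfp = tr_ptc`,
#' `deg_gfp = deg_ptc`, `K_Gli_gfp = K_Gli_ptc`, `K_Pol_gfp = K_Pol_ptc`)
#' unless given explicitly.
#'
#' Units: transcription rates conc/h; translation, degradation, conversion and
#' activation rates 1/h; binding rate `k_ShhPtc` 1/(conc h); affinities
#' (`K_*`) 1/conc; `Km_Ptch1` and `Pol` conc; cooperativities dimensionless.
#' Concentrations are in arbitrary units (the Shh inputs are normalized).
#'
#' @param ... named parameter overrides.
#' @return A named list of class `shh_params`.
#' @examples
#' p <- shh_parameters(c_X = 10)
#' p$deg_GliA
#' @export
shh_parameters <- function(...) {
  defaults <- list(
    tr_ptc = 100, tr_gliFL = 100, tr_x = 1, tr_gfp = NA_real_,
    tl_Ptc = 100, tl_GliFL = 100, tl_X = 1,
    deg_ptc = 2, deg_gliFL = 0.03, deg_x = 1, deg_gfp = NA_real_,
    deg_Ptc = 0.1, deg_GliFL = 0.1, deg_GliA = 1.5, deg_GliR = 0.01,
    deg_X = 0.5,
    conv_GliA = 10, conv_GliR = 0.01, act_Ptc = 10, k_ShhPtc = 100,
    Km_Ptch1 = 1,
    Pol = 1, K_Pol_ptc = 1, K_Pol_gli = 0.01, K_Pol_x = 1,
    K_Pol_gfp = NA_real_,
    K_Gli_ptc = 1, K_Gli_x = 10, K_Gli_gfp = NA_real_, K_X_gli = 10,
    c_GliA = 10, c_GliR = 0, c_X = 0
  )
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]]))
    over <- over[[1L]]
  unknown <- setdiff(names(over), .param_names)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  # reporter promoter inherits the ptch1 promoter unless overridden
  if (is.na(defaults$tr_gfp)) defaults$tr_gfp <- defaults$tr_ptc
  if (is.na(defaults$deg_gfp)) defaults$deg_gfp <- defaults$deg_ptc
  if (is.na(defaults$K_Gli_gfp)) defaults$K_Gli_gfp <- defaults$K_Gli_ptc
  if (is.na(defaults$K_Pol_gfp)) defaults$K_Pol_gfp <- defaults$K_Pol_ptc
  p <- defaults[.param_names]
  validate_parameters(p)
  structure(p, class = "shh_params")
}

#' @rdname shh_parameters
#' @param params a parameter set to validate.
#' @export
validate_parameters <- function(params) {
  vals <- unlist(params[.param_names])
  if (anyNA(vals)) stop("parameter set contains NA")
  if (any(vals < 0)) {
    bad <- .param_names[vals < 0]
    stop("negative parameter(s): ", paste(bad, collapse = ", "))
  }
  if (params$c_GliR != 0)
    stop("c_GliR must be 0: GliR always acts as a strong repressor")
  invisible(params)
}

#' The published reference parameter set
#'
#' The full printed parameter set used for the NIH3T3 fixed-pulse simulation
#' (a distance-zero set from the Gli-transcription posterior with ptch1
#' regulation by Gli reinstated). Shipped as `fig7_parameters.json` in
#' `inst/extdata` with identical values.
#'
#' @param c_X transcriptional strength of the intermediary factor X at the
#'   gli promoter: 0 repressor, 1 neutral, 10 activator.
#' @return A `shh_params` parameter set.
#' @export
reference_parameters <- function(c_X = 0) {
  shh_parameters(c_X = c_X)
}

#' Apply a model-variant's parameter constraints
#'
#' Clamps the parameters a reduced variant removes or ties: variants without
#' the factor X have `tr_x = tl_X = 0`; variants with shared Gli isoform
#' stability set `deg_GliA = deg_GliR = deg_GliFL`. The full variant returns
#' the set unchanged.
#'
#' @param params a `shh_params` set.
#' @param variant one of [model_variants()].
#' @return The constrained `shh_params` set.
#' @export
apply_variant <- function(params, variant = model_variants()) {
  variant <- match.arg(variant)
  p <- unclass(params)
  if (variant %in% c("gli_stability", "ptch1_feedback")) {
    p$tr_x <- 0
    p$tl_X <- 0
    p$c_X <- 0
  }
  if (variant %in% c("ptch1_feedback", "gli_transcription")) {
    p$deg_GliA <- p$deg_GliFL
    p$deg_GliR <- p$deg_GliFL
  }
  structure(p, class = "shh_params")
}

#' @export
print.shh_params <- function(x, ...) {
  cat("Shh pathway parameter set (", length(.param_names), " parameters)\n",
      sep = "")
  v <- unlist(x[.param_names])
  print(v)
  invisible(x)
}

#' Read / write parameter sets as flat JSON
#'
#' Parameter sets are serialized as a flat JSON object keyed by the canonical
#' parameter names.
#'
#' @param path file path.
#' @return `read_parameters` returns a `shh_params` set.
#' @export
read_parameters <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  shh_parameters(as.list(raw[intersect(names(raw), .param_names)]))
}

#' @rdname read_parameters
#' @param params a `shh_params` set.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
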