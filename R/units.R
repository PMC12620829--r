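#' Unit conversions between mass and molar concentration scales
#'
#' Internal model units are nM for concentrations and hours for time;
#' assay-facing quantities (doses in mg, ADA thresholds in ng/mL) are
#' converted at the boundary via molecular weight.
#'
#' @param x numeric vector to convert.
#' @param mw molecular weight in g/mol.
#' @return numeric vector on the target scale.
#' @examples
#' nM_to_ng_per_ml(1, 150000)   # 150 ng/mL for an IgG
#' mg_to_nmol(100, 150000)      # a 100 mg antibody dose in nmol
#' @name units
NULL

#' @rdname units
#' @export
nM_to_ng_per_ml <- function(x, mw) {
  stopifnot(is.numeric(x), is.numeric(mw), mw > 0)
  x * mw * 1e-3
}

#' @rdname units
#' @export
ng_per_ml_to_nM <- function(x, mw) {
  stopifnot(is.numeric(x), is.numeric(mw), mw > 0)
  x * 1e3 / mw
}

#' @rdname units
#' @export
ug_per_ml_to_nM <- function(x, mw) ng_per_ml_to_nM(x * 1e3, mw)

#' @rdname units
#' @export
mg_to_nmol <- function(x, mw) {
  stopifnot(is.numeric(x), is.numeric(mw), mw > 0)
  x * 1e6 / mw
}

# molecular weight of methotrexate, g/mol
MTX_MW <- 454.44

# default molecular weight assumed for the lumped ADA IgG pool, g/mol
ADA_MW_DEFAULT <- 150000
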