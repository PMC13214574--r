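#' Write model parameters to a YAML document
#'
#' The document carries explicit units, the spline knots, the covariate
#' coding and the ICV standardization constants. Numeric values are stored
#' at full double precision (hexadecimal float representation alongside the
#' readable decimal) so a round trip through [read_params_yaml()] is
#' bit-stable.
#'
#' @param p a [model_params()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params_yaml <- function(p, path) {
  validate_params(p)
  num <- function(x) lapply(as.numeric(x), function(v)
    list(value = v, hex = sprintf("%a", v)))
  doc <- list(
    model = "stochastic linear volume/change-rate dynamics",
    units = list(volume = "mm^3", rate = "mm^3/year",
                 acceleration = "mm^3/year^2",
                 fs = "1/year^2", fv = "1/year"),
    sex_coding = p$sex_coding,
    icv_standardization = list(center = num(p$icv_center),
                               scale = num(p$icv_scale)),
    knots_years = num(p$b_spline$knots),
    fs = num(p$fs), fv = num(p$fv),
    b_ctrl = num(p$b_spline$values),
    q_ctrl_unconstrained = num(p$q_spline$values),
    init_mean_coeffs = num(unname(p$init_mean_coeffs)),
    init_cov = num(as.numeric(p$init_cov)),
    sites = names(p$site_biases),
    site_biases = num(unname(p$site_biases)),
    site_noise_sds = num(unname(p$site_noise_sds))
  )
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' Read model parameters from a YAML document
#'
#' @param path file written by [write_params_yaml()].
#' @return a [model_params()] object, bit-identical to the one written.
#' @export
read_params_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  num <- function(x) vapply(x, function(v) {
    h <- suppressWarnings(as.numeric(v$hex))
    if (is.na(h)) v$value else h   # hex floats guarantee bit-stability
  }, numeric(1))
  sites <- as.character(doc$sites)
  model_params(
    fs = num(doc$fs), fv = num(doc$fv),
    b_ctrl = num(doc$b_ctrl),
    q_ctrl = num(doc$q_ctrl_unconstrained),
    init_mean_coeffs = num(doc$init_mean_coeffs),
    init_cov = matrix(num(doc$init_cov), 2, 2),
    site_biases = stats::setNames(num(doc$site_biases), sites),
    site_noise_sds = stats::setNames(num(doc$site_noise_sds), sites),
    knots = num(doc$knots_years),
    icv_center = num(doc$icv_standardization$center),
    icv_scale = num(doc$icv_standardization$scale),
    sex_coding = doc$sex_coding)
}
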