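#' Allometric size standardization
#'
#' Scale a population parameter standardized to a reference body weight down
#' (or up) to an individual of weight `weight`, using the power model
#' \eqn{P_i = P_{std} (W_i / W_{std})^{exp}}. By convention clearances use
#' exponent 0.75 and distribution volumes exponent 1; the reference weight is
#' 70 kg so that small-animal estimates can be compared with adult human
#' values on a common scale.
#'
#' @param p_std standardized parameter value (per `std_weight` kg); must be
#'   strictly positive.
#' @param weight individual body weight in kg; must be strictly positive.
#' @param exponent allometric exponent (0.75 for clearances, 1 for volumes).
#' @param std_weight reference weight in kg (default 70).
#' @return the individual parameter value, same units as `p_std`.
#' @examples
#' scale_allometric(0.135, 4, 0.75)   # clearance for a 4 kg animal
#' scale_allometric(12.3, 4, 1)       # central volume for a 4 kg animal
#' @export
scale_allometric <- function(p_std, weight, exponent, std_weight = 70) {
  if (any(!is.finite(p_std)) || any(p_std <= 0))
    stop("'p_std' must be strictly positive", call. = FALSE)
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("'weight' must be strictly positive", call. = FALSE)
  if (any(!is.finite(exponent)))
    stop("'exponent' must be finite", call. = FALSE)
  if (!is.finite(std_weight) || std_weight <= 0)
    stop("'std_weight' must be strictly positive", call. = FALSE)
  p_std * (weight / std_weight)^exponent
}

#' Total intravenous dose from weight-based dosing
#'
#' @param weight body weight in kg (> 0).
#' @param dose_per_kg dose in mg per kg (>= 0).
#' @return total dose in mg.
#' @examples
#' dose_total(4, 15)  # 60 mg
#' @export
dose_total <- function(weight, dose_per_kg) {
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("'weight' must be strictly positive", call. = FALSE)
  if (any(!is.finite(dose_per_kg)) || any(dose_per_kg < 0))
    stop("'dose_per_kg' must be non-negative", call. = FALSE)
  weight * dose_per_kg
}

#' Injection formulation volumes
#'
#' The intravenous solution is prepared from a per-milligram recipe: each mg
#' of drug is dissolved in 0.060 ml of 0.075 M HCl and then diluted in
#' 0.200 ml of 20\% N,N-dimethylacetamide. Volumes scale linearly with the
#' total dose.
#'
#' @param dose_mg total dose in mg (>= 0).
#' @return named numeric vector with components `acid_ml`, `diluent_ml`,
#'   `total_ml`.
#' @examples
#' formulation_volumes(60)  # 3.6, 12, 15.6 ml
#' @export
formulation_volumes <- function(dose_mg) {
  if (any(!is.finite(dose_mg)) || any(dose_mg < 0))
    stop("'dose_mg' must be non-negative", call. = FALSE)
  acid <- 0.060 * dose_mg
  dil <- 0.200 * dose_mg
  c(acid_ml = acid, diluent_ml = dil, total_ml = acid + dil)
}
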