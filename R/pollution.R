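#' Quartile scores for pollutant emission levels
#'
#' Assigns each garden an integer score from 1 (lowest quartile of emission
#' values) to 4 (highest quartile). Ties are ranked with average ranks and the
#' ranks are cut at their 25/50/75 percentiles with an inclusive lower bound,
#' so an all-equal input yields score 1 everywhere.
#'
#' @param values Numeric vector of per-garden emission levels.
#' @return Integer vector of scores in `1:4`, same length as `values`.
#' @export
#' @examples
#' quartile_scores(c(1, 2, 3, 4))
quartile_scores <- function(values) {
  if (sum(is.finite(values)) < 1L) {
    stop("quartile_scores() needs at least one finite value", call. = FALSE)
  }
  r <- rank(values, na.last = "keep")
  qs <- quantile(r, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  as.integer(1L + (r > qs[1]) + (r > qs[2]) + (r > qs[3]))
}

#' Raw atmospheric pollution variable
#'
#' Summed air-quality quartile scores for NO2, PM2.5 and PM10 divided by the
#' distance to the nearest highway.
#'
#' @param q_no2,q_pm25,q_pm10 Integer quartile scores in `1:4`.
#' @param d_highway Distance to the nearest highway (m), strictly positive.
#' @return Numeric, score per metre.
#' @export
#' @examples
#' var_atmo(4, 2, 2, 183)
var_atmo <- function(q_no2, q_pm25, q_pm10, d_highway) {
  scores <- c(q_no2, q_pm25, q_pm10)
  if (!all(scores %in% 1:4)) {
    stop("quartile scores must be integers in 1..4", call. = FALSE)
  }
  if (any(d_highway <= 0)) stop("d_highway must be > 0", call. = FALSE)
  (q_no2 + q_pm25 + q_pm10) / d_highway
}

#' Raw agricultural pollution variable
#'
#' Squared area of the nearest agricultural zone divided by the distance to
#' it.
#'
#' @param agri_surface Area of the nearest agricultural zone (>= 0).
#' @param d_agri Distance to the nearest agricultural area (m), > 0.
#' @return Numeric.
#' @export
var_agri <- function(agri_surface, d_agri) {
  if (any(agri_surface < 0)) stop("agri_surface must be >= 0", call. = FALSE)
  if (any(d_agri <= 0)) stop("d_agri must be > 0", call. = FALSE)
  agri_surface^2 / d_agri
}

#' Raw industrial pollution variable
#'
#' Reciprocal of the distance to the nearest industrial area.
#'
#' @param d_indus Distance to the nearest industrial area (m), > 0.
#' @return Numeric, 1/m.
#' @export
#' @examples
#' round(var_indus(528), 4)
var_indus <- function(d_indus) {
  if (any(d_indus <= 0)) stop("d_indus must be > 0", call. = FALSE)
  1 / d_indus
}

#' Min-max normalization to \[0, 1\]
#'
#' Maps `x` to `(x - min) / (max - min)`. When all values are equal the range
#' is degenerate and every value is defined as 0, with a warning.
#'
#' @param x Numeric vector (>= 2 values).
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values to normalize", call. = FALSE)
  rng <- range(x, na.rm = TRUE)
  if (rng[1] == rng[2]) {
    warning("all values equal; normalized values set to 0")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Per-garden pollution variables
#'
#' Computes the raw atmospheric, agricultural and industrial pollution
#' variables for a set of gardens and min-max-normalizes each variable across
#' the garden set. Accepts either the three separate air-quality quartile
#' scores (`q_no2`, `q_pm25`, `q_pm10`) or their printed sum (`atmo_score`).
#' The agricultural variable is only computed when `agri_surface` is present
#' (the published table prints the variable but not the underlying surface).
#'
#' @param gardens Data frame with columns `garden_id`, `d_highway`, `d_indus`,
#'   and either `atmo_score` or `q_no2` + `q_pm25` + `q_pm10`; optionally
#'   `d_agri` and `agri_surface`.
#' @return Data frame with raw (`var_atmo`, `var_agri`, `var_indus`) and
#'   normalized (`*_norm`) columns.
#' @export
pollution_variables <- function(gardens) {
  req <- c("garden_id", "d_highway", "d_indus")
  miss <- setdiff(req, names(gardens))
  if (length(miss)) stop("gardens is missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (all(c("q_no2", "q_pm25", "q_pm10") %in% names(gardens))) {
    atmo_score <- gardens$q_no2 + gardens$q_pm25 + gardens$q_pm10
  } else if ("atmo_score" %in% names(gardens)) {
    atmo_score <- gardens$atmo_score
  } else {
    stop("gardens needs either q_no2/q_pm25/q_pm10 or atmo_score", call. = FALSE)
  }
  if (any(gardens$d_highway <= 0) || any(gardens$d_indus <= 0)) {
    stop("distances must be > 0", call. = FALSE)
  }
  out <- data.frame(garden_id = gardens$garden_id,
                    var_atmo = atmo_score / gardens$d_highway,
                    var_indus = var_indus(gardens$d_indus))
  if ("agri_surface" %in% names(gardens)) {
    out$var_agri <- var_agri(gardens$agri_surface, gardens$d_agri)
  }
  for (v in intersect(c("var_atmo", "var_agri", "var_indus"), names(out))) {
    out[[paste0(v, "_norm")]] <- minmax_normalize(out[[v]])
  }
  out
}
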