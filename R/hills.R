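#' Metadynamics configuration
#'
#' Discrete Gaussian deposition approximating continuous metadynamics: every
#' `stride` ps a hill of height `deposition_rate * stride` is added at the
#' current (S, Z).
#'
#' @param deposition_rate Bias deposition rate, kcal mol^-1 ps^-1
#'   (default 0.1).
#' @param stride Time between deposits in ps (default 1).
#' @param sigma_s Gaussian width along S (dimensionless, default 0.15).
#' @param sigma_z Gaussian width along Z in A^2 (default 0.20).
#' @return A list of class `"metad_config"`; the implied hill height is in
#'   `$height`.
#' @export
metad_config <- function(deposition_rate = 0.1, stride = 1,
                         sigma_s = 0.15, sigma_z = 0.20) {
  if (deposition_rate < 0) stop("deposition_rate must be >= 0")
  if (stride <= 0 || sigma_s <= 0 || sigma_z <= 0)
    stop("stride and widths must be positive")
  structure(list(deposition_rate = deposition_rate, stride = stride,
                 sigma_s = sigma_s, sigma_z = sigma_z,
                 height = deposition_rate * stride),
            class = "metad_config")
}

#' Hill log constructor
#'
#' @param time Deposit times (ps), non-decreasing.
#' @param s,z Hill centres.
#' @param height Hill heights in kcal/mol (> 0), recycled.
#' @param sigma_s,sigma_z Widths, recycled.
#' @return A data frame of class `"hill_log"`.
#' @export
hill_log <- function(time, s, z, height, sigma_s, sigma_z) {
  h <- data.frame(time = time, s = s, z = z,
                  height = rep_len(height, length(time)),
                  sigma_s = rep_len(sigma_s, length(time)),
                  sigma_z = rep_len(sigma_z, length(time)))
  if (is.unsorted(h$time)) stop("hill times must be non-decreasing")
  if (any(h$height <= 0)) stop("hill heights must be positive")
  class(h) <- c("hill_log", class(h))
  h
}

#' Accumulated bias potential from a hill log
#'
#' `V(s, z, t) = sum over hills deposited before t of
#' h exp(-(s - s_k)^2 / (2 sigma_s^2)) exp(-(z - z_k)^2 / (2 sigma_z^2))`.
#' Exact (non-gridded) sum; `bias_gradient()` gives the analytic
#' (dV/ds, dV/dz).
#'
#' @param s,z Evaluation point (scalars).
#' @param hills A [hill_log()] (possibly empty).
#' @param t Only hills with `time < t` contribute; default all.
#' @return Bias in kcal/mol (`bias_value`) or `c(dVds, dVdz)`
#'   (`bias_gradient`).
#' @export
bias_value <- function(s, z, hills, t = Inf) {
  if (!nrow(hills)) return(0)
  k <- hills$time < t
  if (!any(k)) return(0)
  h <- hills[k, ]
  sum(h$height * exp(-(s - h$s)^2 / (2 * h$sigma_s^2)
                     - (z - h$z)^2 / (2 * h$sigma_z^2)))
}

#' @rdname bias_value
#' @export
bias_gradient <- function(s, z, hills, t = Inf) {
  if (!nrow(hills)) return(c(0, 0))
  k <- hills$time < t
  if (!any(k)) return(c(0, 0))
  h <- hills[k, ]
  g <- h$height * exp(-(s - h$s)^2 / (2 * h$sigma_s^2)
                      - (z - h$z)^2 / (2 * h$sigma_z^2))
  c(-sum(g * (s - h$s) / h$sigma_s^2), -sum(g * (z - h$z) / h$sigma_z^2))
}

#' Write / read a hill log as a PLUMED-style whitespace table
#'
#' Columns: time, s, z, sigma_s, sigma_z, height, preceded by a
#' `#! FIELDS` header line.
#'
#' @param hills A [hill_log()].
#' @param path File path.
#' @return `path` (write) or a [hill_log()] (read).
#' @export
write_hills <- function(hills, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time s z sigma_s sigma_z height", con)
  writeLines(sprintf("%.6f %.10g %.10g %.6g %.6g %.6g", hills$time, hills$s,
                     hills$z, hills$sigma_s, hills$sigma_z, hills$height), con)
  invisible(path)
}

#' @rdname write_hills
#' @export
read_hills <- function(path) {
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("time", "s", "z", "sigma_s", "sigma_z",
                                  "height"))
  hill_log(tab$time, tab$s, tab$z, tab$height, tab$sigma_s, tab$sigma_z)
}
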