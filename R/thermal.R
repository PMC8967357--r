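#' Beta-function thermal response
#'
#' Dimensionless temperature response in \[0, 1\] used for leaf tip
#' appearance and leaf elongation rates: zero at or below `t_base` and at
#' or above `t_ceil`, and exactly 1 at `t_opt`. The shape is the standard
#' beta form used throughout process-based crop models,
#' \deqn{f(T) = \frac{T_c - T}{T_c - T_o}
#'       \left(\frac{T - T_b}{T_o - T_b}\right)^{(T_o - T_b)/(T_c - T_o)}.}
#'
#' @param temp temperature (degC); vectorized.
#' @param t_base,t_opt,t_ceil cardinal temperatures (degC),
#'   `t_base < t_opt < t_ceil`.
#' @return numeric vector of factors in \[0, 1\].
#' @examples
#' thermal_response(22)            # 1 at the optimum
#' thermal_response(c(-5, 0, 34))  # 0 outside the viable range
#' @export
thermal_response <- function(temp, t_base = 0, t_opt = 22, t_ceil = 34) {
  stopifnot(t_base < t_opt, t_opt < t_ceil)
  f <- rep(0, length(temp))
  ok <- temp > t_base & temp < t_ceil
  tt <- temp[ok]
  ex <- (t_opt - t_base) / (t_ceil - t_opt)
  f[ok] <- ((t_ceil - tt) / (t_ceil - t_opt)) *
    ((tt - t_base) / (t_opt - t_base))^ex
  pmin(pmax(f, 0), 1)
}
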