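#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rpois runif qnorm pnorm pt qt sd median quantile
#'   setNames complete.cases
#' @importFrom utils write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_if_not_scalar <- function(x, name, lower = -Inf, upper = Inf,
                               strict_lower = FALSE) {
  if (!is_scalar_num(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  bad <- if (strict_lower) x <= lower else x < lower
  if (bad || x > upper)
    stop(sprintf("'%s' = %g is outside its allowed range", name, x),
         call. = FALSE)
  invisible(x)
}

# Shift a matrix by (dy, dx), padding with `fill`.  dy > 0 moves content down
# (toward larger row index), dx > 0 moves right.
shift_mat <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  src_r <- seq_len(h) - dy
  src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1 & src_r <= h
  ok_c <- src_c >= 1 & src_c <= w
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# 3x3 box sum via shifts (used to pool Hough votes across neighbouring cells).
boxsum3 <- function(m) {
  out <- matrix(0, nrow(m), ncol(m))
  for (dy in -1:1) for (dx in -1:1) out <- out + shift_mat(m, dy, dx)
  out
}

# Angular membership test for arcs given in degrees in [0, 360); an arc may
# wrap through 0.  End angle of 360 denotes the full circle together with
# start 0.
in_arc <- function(angle_deg, start_deg, end_deg) {
  a <- angle_deg %% 360
  s <- start_deg %% 360
  e <- if (end_deg == 360 && start_deg == 0) 360 else end_deg %% 360
  if (s < e || (s == 0 && e == 360)) a >= s & a < e else a >= s | a < e
}

arc_length_deg <- function(start_deg, end_deg) {
  if (end_deg == 360 && start_deg == 0) return(360)
  (end_deg - start_deg) %% 360
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
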