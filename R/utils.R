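# Small shared numeric helpers. Angles are mathematical radians
# (counter-clockwise from +x); turning angles live in (-pi, pi].

#' Wrap an angle into (-pi, pi]
#'
#' @param a numeric vector of angles in radians.
#' @return angles congruent to `a` modulo 2*pi, in (-pi, pi].
#' @keywords internal
wrap_pi <- function(a) {
  r <- ((a + pi) %% (2 * pi)) - pi
  r[r == -pi] <- pi
  r
}

#' Bearing of a displacement
#' @param dx,dy displacement components in metres.
#' @return angle in radians, counter-clockwise from +x.
#' @keywords internal
bearing_of <- function(dx, dy) atan2(dy, dx)

# log(sum(exp(x))) guarded against overflow
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# deep merge for config lists: values in `new` override `base`
merge_config <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(base[[nm]]) && is.list(new[[nm]]) && !is.data.frame(new[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}
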