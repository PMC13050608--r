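.isColor <- function(x) {
  grepl("^#([0-9a-fA-F]{6}|[0-9a-fA-F]{8})$", x) | x %in% grDevices::colors()
}

.toHex <- function(x) {
  rgb <- grDevices::col2rgb(x)
  sprintf("#%02x%02x%02x", rgb[1, ], rgb[2, ], rgb[3, ])
}

#' Assign categorical colors to labels
#'
#' Deterministic: user overrides win; remaining labels receive the scheme's
#' colors cycled in label order (label `i` gets scheme color
#' `((i - 1) mod scheme size) + 1`).
#'
#' @param labels character vector of labels.
#' @param overrides named character vector label -> color; malformed colors
#'   are rejected.
#' @param scheme qualitative palette name understood by
#'   `grDevices::palette.colors` (default `"Okabe-Ito"`).
#' @return named character vector of hex colors, one per label.
#' @examples
#' assignColors(c("T", "B"), overrides = c(T = "#ff0000"))
#' @export
assignColors <- function(labels, overrides = character(),
                         scheme = "Okabe-Ito") {
  labels <- as.character(labels)
  base <- grDevices::palette.colors(palette = scheme)
  out <- .toHex(base[((seq_along(labels) - 1L) %% length(base)) + 1L])
  names(out) <- labels
  overrides <- overrides[names(overrides) %in% labels]
  if (length(overrides)) {
    bad <- !.isColor(overrides)
    if (any(bad))
      stopConfig("malformed color '%s' for label '%s'",
                 overrides[bad][1L], names(overrides)[bad][1L])
    out[names(overrides)] <- .toHex(unname(overrides))
  }
  out
}

## Continuous heatmap ramp: linear on the (possibly log-transformed) value
## range; color index is a monotone step function of the value.
.heatRamp <- function(values, scheme = "Viridis", n = 256L) {
  pal <- grDevices::hcl.colors(n, scheme)
  rng <- range(values, finite = TRUE)
  if (!is.finite(rng[1]) || rng[1] == rng[2])
    return(stats::setNames(rep(pal[n %/% 2L], length(values)), NULL))
  idx <- 1L + as.integer(floor((values - rng[1]) / (rng[2] - rng[1]) *
                                 (n - 1L)))
  pal[pmin(pmax(idx, 1L), n)]
}
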