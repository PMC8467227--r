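#' The 55-column CSR fingerprint layout
#'
#' Family GH13 alpha-amylases carry eight conserved sequence regions (CSRs)
#' associated with the beta-strands of the catalytic TIM-barrel. Concatenated
#' in their order of appearance along the sequence (beta1 to beta8, i.e.
#' CSR-VIII, VI, I, V, II, III, IV, VII) they form a 55-character fingerprint.
#' `csr_layout()` returns the default partition of fingerprint columns 1-55
#' into the eight CSR spans together with the landmark positions: the
#' catalytic triad at columns 28 (Asp, nucleophile), 37 (Glu, proton donor)
#' and 46 (Asp, transition-state stabilizer), and the chloride-binding triad
#' at columns 26 (Arg), 44 (Asn) and 50 (Arg/Lys).
#'
#' @param spans Named list of integer vectors `c(start, end)` in fingerprint
#'   coordinates, one per CSR, in sequence order. Rarely overridden.
#' @return An object of class `csr_layout`: list with elements `spans`
#'   (named list of `c(start, end)`), `order` (CSR names in sequence order),
#'   `width` (total fingerprint width), `triad` (named landmark columns) and
#'   `chloride` (named landmark columns).
#' @examples
#' lay <- csr_layout()
#' lay$width            # 55
#' lay$spans[["CSR-II"]] # columns 24..32
#' @export
csr_layout <- function(spans = list(
                         "CSR-VIII" = c(1L, 3L),
                         "CSR-VI"   = c(4L, 12L),
                         "CSR-I"    = c(13L, 18L),
                         "CSR-V"    = c(19L, 23L),
                         "CSR-II"   = c(24L, 32L),
                         "CSR-III"  = c(33L, 40L),
                         "CSR-IV"   = c(41L, 46L),
                         "CSR-VII"  = c(47L, 55L)
                       )) {
  stopifnot(is.list(spans), !is.null(names(spans)))
  ord <- names(spans)
  starts <- vapply(spans, function(s) as.integer(s[1]), integer(1))
  ends <- vapply(spans, function(s) as.integer(s[2]), integer(1))
  if (any(ends < starts)) stop("CSR span with end < start")
  # spans must be contiguous and cover 1..width exactly
  if (starts[1] != 1L) stop("layout must start at fingerprint column 1")
  if (length(spans) > 1 && any(starts[-1] != ends[-length(ends)] + 1L)) {
    stop("CSR spans must be contiguous and disjoint")
  }
  width <- unname(ends[length(ends)])
  triad <- c(nucleophile = 28L, proton_donor = 37L, stabilizer = 46L)
  chloride <- c(arg1 = 26L, asn = 44L, arg2 = 50L)
  lay <- structure(
    list(spans = spans, order = ord, width = width,
         triad = triad, chloride = chloride),
    class = "csr_layout"
  )
  validate_layout(lay)
  lay
}

validate_layout <- function(lay) {
  in_span <- function(pos, csr) {
    s <- lay$spans[[csr]]
    pos >= s[1] && pos <= s[2]
  }
  if (lay$width < max(c(lay$triad, lay$chloride))) {
    stop("layout narrower than its landmark positions")
  }
  ok <- in_span(lay$triad[["nucleophile"]], "CSR-II") &&
    in_span(lay$triad[["proton_donor"]], "CSR-III") &&
    in_span(lay$triad[["stabilizer"]], "CSR-IV") &&
    in_span(lay$chloride[["arg1"]], "CSR-II") &&
    in_span(lay$chloride[["asn"]], "CSR-IV") &&
    in_span(lay$chloride[["arg2"]], "CSR-VII")
  if (!ok) stop("landmark positions fall outside their CSR spans")
  invisible(lay)
}

#' Width of each CSR span in a layout
#' @param lay A `csr_layout`.
#' @return Named integer vector of span widths, in sequence order.
#' @export
csr_span_widths <- function(lay = csr_layout()) {
  vapply(lay$spans, function(s) s[2] - s[1] + 1L, integer(1))
}

#' @export
print.csr_layout <- function(x, ...) {
  cat("CSR fingerprint layout,", x$width, "columns\n")
  for (nm in x$order) {
    s <- x$spans[[nm]]
    cat(sprintf("  %-9s %2d-%2d\n", nm, s[1], s[2]))
  }
  cat("catalytic triad:", paste(x$triad, collapse = "/"),
      " chloride triad:", paste(x$chloride, collapse = "/"), "\n")
  invisible(x)
}

# internal: the 20-letter amino-acid alphabet used throughout
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")
GH13_SUBFAMILIES <- c("GH13_1", "GH13_5", "GH13_15",
                      "GH13_24", "GH13_32", "GH13_42")
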