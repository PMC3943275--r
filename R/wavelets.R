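# Orthonormal Daubechies scaling filters h (sum = sqrt(2)).  "dbJ" has J
# vanishing moments and 2J taps; db4 is the codec default.  The highpass
# decomposition filter is derived by the quadrature-mirror relation
# g[k] = (-1)^k h[T-1-k].
.db_filters <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314453416, 0.8365163037378079, 0.2241438680420134,
          -0.12940952255126037),
  db3 = c(0.33267055295008263, 0.8068915093110925, 0.45987750211849154,
          -0.13501102001025458, -0.08544127388202666, 0.03522629188570953),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032),
  db5 = c(0.16010239797419293, 0.6038292697971896, 0.7243085284377729,
          0.13842814590132074, -0.24229488706638203, -0.032244869584638375,
          0.07757149384004572, -0.006241490212798274, -0.012580751999081999,
          0.0033357252854737712),
  db6 = c(0.11154074335010947, 0.49462389039845306, 0.7511339080210954,
          0.31525035170919763, -0.22626469396543983, -0.12976686756726194,
          0.09750160558732304, 0.027522865530305727, -0.03158203931748603,
          0.0005538422011614961, 0.004777257510945511, -0.0010773010853084796),
  db8 = c(0.05441584224310401, 0.31287159091429995, 0.6756307362972898,
          0.5853546836542067, -0.015829105256349306, -0.2840155429615469,
          0.0004724845739132828, 0.12874742662047847, -0.017369301001807547,
          -0.044088253930794755, 0.013981027917398282, 0.008746094047405777,
          -0.004870352993451574, -0.00039174037337694705,
          0.0006754494064505693, -0.00011747678412476953)
)

#' Wavelet filter pair
#'
#' Returns the orthonormal lowpass/highpass decomposition filter pair for a
#' Daubechies wavelet.
#'
#' @param wavelet Wavelet name, one of `"db1"` ... `"db6"`, `"db8"`.
#' @return List with components `h` (lowpass) and `g` (highpass), each a
#'   numeric vector of the same even length.
#' @export
wavelet_filters <- function(wavelet = "db4") {
  h <- .db_filters[[wavelet]]
  if (is.null(h)) {
    stop("unknown wavelet '", wavelet, "'; available: ",
         paste(names(.db_filters), collapse = ", "), call. = FALSE)
  }
  taps <- length(h)
  g <- rev(h) * (-1)^(seq_len(taps) - 1)
  list(h = h, g = g)
}
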