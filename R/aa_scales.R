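#' Per-residue amino-acid scale tables
#'
#' Fourteen published per-residue scales used to build sequence-derived
#' features for donor motifs and for windows of the recipient protein around
#' each insertion site. Each scale maps the 20 canonical amino acids
#' (one-letter codes) to a numeric value:
#'
#' * `molecular_weight` — residue molecular weight (Da).
#' * `surface_area` — standard-state accessible surface area (A^2; Chothia).
#' * `alpha_propensity`, `beta_propensity`, `reverse_turn` — Chou--Fasman
#'   conformational propensities.
#' * `buried_accessibility` — buried/accessible ratio (Janin).
#' * `flexibility` — average backbone flexibility (Bhaskaran--Ponnuswamy).
#' * `hydropathy` — Kyte--Doolittle hydropathy index.
#' * `hydrophobicity` — Eisenberg consensus hydrophobicity.
#' * `negative_charge`, `positive_charge` — indicator-style charge scales
#'   (histidine counted as 0.1 positive at neutral pH).
#' * `pka` — alpha-carboxyl pKa.
#' * `polarity` — Grantham polarity.
#' * `volume` — residue volume (A^3; Zamyatnin).
#'
#' @return `aa_scales()` returns a named list of 14 named numeric vectors;
#'   `scale_table(name)` returns one of them.
#' @examples
#' scale_table("hydropathy")[["A"]]  # 1.8
#' @export
aa_scales <- function() .aa_scales

#' @rdname aa_scales
#' @param name Scale name, one of `names(aa_scales())`.
#' @export
scale_table <- function(name) {
  if (!name %in% names(.aa_scales)) {
    stopf("unknown scale '%s'; available: %s", name,
          paste(names(.aa_scales), collapse = ", "))
  }
  .aa_scales[[name]]
}

.aa_order <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.mk_scale <- function(...) {
  v <- c(...)
  stopifnot(identical(sort(names(v)), sort(.aa_order)))
  v[.aa_order]
}

.aa_scales <- list(
  molecular_weight = .mk_scale(
    A = 89.09, R = 174.20, N = 132.12, D = 133.10, C = 121.16,
    E = 147.13, Q = 146.15, G = 75.07, H = 155.16, I = 131.17,
    L = 131.17, K = 146.19, M = 149.21, F = 165.19, P = 115.13,
    S = 105.09, T = 119.12, W = 204.23, Y = 181.19, V = 117.15),
  surface_area = .mk_scale(
    A = 115, R = 225, N = 160, D = 150, C = 135,
    E = 190, Q = 180, G = 75, H = 195, I = 175,
    L = 170, K = 200, M = 185, F = 210, P = 145,
    S = 115, T = 140, W = 255, Y = 230, V = 155),
  alpha_propensity = .mk_scale(
    A = 1.42, R = 0.98, N = 0.67, D = 1.01, C = 0.70,
    E = 1.51, Q = 1.11, G = 0.57, H = 1.00, I = 1.08,
    L = 1.21, K = 1.16, M = 1.45, F = 1.13, P = 0.57,
    S = 0.77, T = 0.83, W = 1.08, Y = 0.69, V = 1.06),
  beta_propensity = .mk_scale(
    A = 0.83, R = 0.93, N = 0.89, D = 0.54, C = 1.19,
    E = 0.37, Q = 1.10, G = 0.75, H = 0.87, I = 1.60,
    L = 1.30, K = 0.74, M = 1.05, F = 1.38, P = 0.55,
    S = 0.75, T = 1.19, W = 1.37, Y = 1.47, V = 1.70),
  buried_accessibility = .mk_scale(
    A = 1.7, R = 0.1, N = 0.4, D = 0.4, C = 4.6,
    E = 0.3, Q = 0.3, G = 1.8, H = 0.8, I = 3.1,
    L = 2.4, K = 0.05, M = 1.9, F = 2.2, P = 0.6,
    S = 0.8, T = 0.7, W = 1.6, Y = 0.5, V = 2.9),
  flexibility = .mk_scale(
    A = 0.357, R = 0.529, N = 0.463, D = 0.511, C = 0.346,
    E = 0.497, Q = 0.493, G = 0.544, H = 0.323, I = 0.462,
    L = 0.365, K = 0.466, M = 0.295, F = 0.314, P = 0.509,
    S = 0.507, T = 0.444, W = 0.305, Y = 0.420, V = 0.386),
  hydropathy = .mk_scale(
    A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
    E = -3.5, Q = -3.5, G = -0.4, H = -3.2, I = 4.5,
    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2),
  hydrophobicity = .mk_scale(
    A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
    E = -0.74, Q = -0.85, G = 0.48, H = -0.40, I = 1.38,
    L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
    S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08),
  negative_charge = .mk_scale(
    A = 0, R = 0, N = 0, D = 1, C = 0, E = 1, Q = 0, G = 0, H = 0, I = 0,
    L = 0, K = 0, M = 0, F = 0, P = 0, S = 0, T = 0, W = 0, Y = 0, V = 0),
  pka = .mk_scale(
    A = 2.34, R = 2.17, N = 2.02, D = 1.88, C = 1.96,
    E = 2.19, Q = 2.17, G = 2.34, H = 1.82, I = 2.36,
    L = 2.36, K = 2.18, M = 2.28, F = 1.83, P = 1.99,
    S = 2.21, T = 2.09, W = 2.83, Y = 2.20, V = 2.32),
  polarity = .mk_scale(
    A = 8.1, R = 10.5, N = 11.6, D = 13.0, C = 5.5,
    E = 12.3, Q = 10.5, G = 9.0, H = 10.4, I = 5.2,
    L = 4.9, K = 11.3, M = 5.7, F = 5.2, P = 8.0,
    S = 9.2, T = 8.6, W = 5.4, Y = 6.2, V = 5.9),
  positive_charge = .mk_scale(
    A = 0, R = 1, N = 0, D = 0, C = 0, E = 0, Q = 0, G = 0, H = 0.1, I = 0,
    L = 0, K = 1, M = 0, F = 0, P = 0, S = 0, T = 0, W = 0, Y = 0, V = 0),
  reverse_turn = .mk_scale(
    A = 0.66, R = 0.95, N = 1.56, D = 1.46, C = 1.19,
    E = 0.74, Q = 0.98, G = 1.56, H = 0.95, I = 0.47,
    L = 0.59, K = 1.01, M = 0.60, F = 0.60, P = 1.52,
    S = 1.43, T = 0.96, W = 0.96, Y = 1.14, V = 0.50),
  volume = .mk_scale(
    A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
    E = 138.4, Q = 143.8, G = 60.1, H = 153.2, I = 166.7,
    L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
    S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)
)
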