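# Single-bond covalent radii (Angstrom), Cordero et al. consensus values for
# the common organic/bioinorganic elements, and bond-order scale factors.
# single 1.00, aromatic 0.915, double 0.87, triple 0.78 -- chosen so the C
# radius reproduces benzene (~1.39 A), ethene (~1.32 A) and ethyne (~1.19 A).

.covalent_radius <- c(
  H = 0.31, He = 0.28,
  Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
  K = 2.03, Ca = 1.76, Zn = 1.22, Ga = 1.22, Ge = 1.20, As = 1.19, Se = 1.20,
  Br = 1.20, I = 1.39, Sn = 1.39, Sb = 1.39, Te = 1.38
)

.order_factor <- c(`1` = 1.00, `4` = 0.915, `2` = 0.87, `3` = 0.78)

#' Ideal bond length from covalent radii
#'
#' Sum of the two elements' single-bond covalent radii, scaled by a fixed
#' factor per bond order (single 1.00, aromatic 0.915, double 0.87,
#' triple 0.78). Symmetric in its element arguments.
#'
#' @param elem_a,elem_b element symbols.
#' @param order bond order: 1, 2, 3, or `"ar"` / 4 for aromatic.
#' @return ideal length in Angstrom.
#' @examples
#' ideal_bond_length("C", "C", 1)  # 1.52
#' ideal_bond_length("C", "O", 1)  # 1.42
#' @export
ideal_bond_length <- function(elem_a, elem_b, order = 1L) {
  ra <- .covalent_radius[elem_a]
  rb <- .covalent_radius[elem_b]
  if (any(is.na(ra)) || any(is.na(rb))) {
    missing <- unique(c(elem_a[is.na(ra)], elem_b[is.na(rb)]))
    stop("no covalent radius for element(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ord <- as.character(ifelse(order == "ar", 4L, as.integer(order)))
  f <- .order_factor[ord]
  if (any(is.na(f))) stop("unknown bond order: ", paste(order, collapse = ", "), call. = FALSE)
  unname((ra + rb) * f)
}

# Ideal length for a specific bond of a molecule (aromatic flag wins over the
# stored Kekule order).
#' @noRd
ideal_length_for_bond <- function(mol, k) {
  ord <- if (mol$bonds$aromatic[k]) 4L else mol$bonds$order[k]
  ideal_bond_length(mol$atoms$element[mol$bonds$a[k]],
                    mol$atoms$element[mol$bonds$b[k]], ord)
}
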