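#' Subunit table for the yeast basket symmetry unit
#'
#' One symmetry unit of the yeast nuclear basket: the two Mlp coiled-coil
#' proteins (the stoichiometry of Mlp1 versus Mlp2 is ambiguous, so both
#' are carried as generic poly-alanine chains of Mlp1's length), the FG
#' nucleoporins Nup1 (one copy), Nup2 and Nup60 (two copies each, FG
#' repeats excluded from the representation), and two copies of the
#' heptameric Nup84 complex of the nuclear ring. Totals: 21 subunit
#' instances of 12 distinct types per symmetry unit.
#'
#' Lengths are UniProt sequence lengths; FG-segment boundaries are
#' round-number annotations adequate for coarse-grained modeling.
#'
#' @return List of [subunit_spec()] objects.
#' @export
yeast_basket_specs <- function() {
  seg <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(first = as.integer(m[, 1]), last = as.integer(m[, 2]),
               kind = SEGMENT_KINDS[as.integer(m[, 3])])
  }
  cc <- 2L; dis <- 3L; exc <- 4L; rig <- 1L
  y <- list(
    # Mlp1/Mlp2: long coiled-coil rods with a disordered C-terminal domain
    subunit_spec("Mlp1", 1875, copies = 1,
                 segments = seg(1, 1460, cc, 1461, 1875, dis)),
    subunit_spec("Mlp2", 1875, copies = 1,   # length set to Mlp1's
                 segments = seg(1, 1460, cc, 1461, 1875, dis)),
    subunit_spec("Nup1", 1076, copies = 1,
                 segments = seg(1, 350, dis, 351, 1076, exc)),
    subunit_spec("Nup2", 720, copies = 2,
                 segments = seg(1, 180, dis, 181, 560, exc, 561, 720, dis)),
    subunit_spec("Nup60", 539, copies = 2,
                 segments = seg(1, 380, dis, 381, 539, exc))
  )
  y84 <- c(Nup84 = 726, Nup85 = 744, Nup120 = 1037, Nup133 = 1157,
           Nup145C = 712, Seh1 = 349, Sec13 = 297)
  c(y, lapply(names(y84), function(nm)
    subunit_spec(nm, y84[[nm]], copies = 2,
                 segments = seg(1, y84[[nm]], rig))))
}

#' Subunit table for the mammalian basket symmetry unit
#'
#' One symmetry unit of the mammalian basket: two copies each of Tpr,
#' Nup50 and Nup153 (FG repeats excluded), plus two copies of the
#' nonameric Nup107 complex of the nuclear ring. Totals: 24 subunit
#' instances of 12 distinct types per symmetry unit.
#'
#' @return List of [subunit_spec()] objects.
#' @export
mouse_basket_specs <- function() {
  seg <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(first = as.integer(m[, 1]), last = as.integer(m[, 2]),
               kind = SEGMENT_KINDS[as.integer(m[, 3])])
  }
  cc <- 2L; dis <- 3L; exc <- 4L; rig <- 1L
  m <- list(
    subunit_spec("Tpr", 2363, copies = 2,
                 segments = seg(1, 1630, cc, 1631, 2363, dis)),
    subunit_spec("Nup50", 469, copies = 2,
                 segments = seg(1, 220, dis, 221, 469, exc)),
    subunit_spec("Nup153", 1475, copies = 2,
                 segments = seg(1, 650, dis, 651, 1475, exc))
  )
  m107 <- c(Nup107 = 925, Nup96 = 936, Nup160 = 1436, Nup133m = 1156,
            Nup85m = 656, Nup37 = 326, Nup43 = 380, Seh1m = 360,
            Sec13m = 322)
  c(m, lapply(names(m107), function(nm)
    subunit_spec(nm, m107[[nm]], copies = 2,
                 segments = seg(1, m107[[nm]], rig))))
}
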