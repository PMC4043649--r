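#' Antibody panel and population definitions
#'
#' The panel models an 8-detector murine whole-blood myeloid stain: forward and
#' side scatter plus six fluorescence detectors carrying CD43 (FITC), a PE
#' lineage dump channel (Ly6G/CD90.2/B220/CD49b/NK1.1), MHC-II (PE-Cy7),
#' F4/80 (APC), CD11b (AlexaFluor700, also the counting-bead carrier) and
#' Ly6C (Pacific Blue).
#'
#' @name panel
#' @keywords internal
NULL

cyto_channels <- function() c("FSC", "SSC", "CD43", "Lin", "MHCII", "F480", "CD11b", "Ly6C")

cyto_fluor_channels <- function() c("CD43", "Lin", "MHCII", "F480", "CD11b", "Ly6C")

cyto_scatter_channels <- function() c("FSC", "SSC")

cyto_detectors <- function() {
  c(FSC = "FSC-A", SSC = "SSC-A", CD43 = "FITC-A", Lin = "PE-A",
    MHCII = "PE-Cy7-A", F480 = "APC-A", CD11b = "AF700-A", Ly6C = "PacBlue-A")
}

#' Leukocyte populations modelled by the generator
#'
#' @return Character vector of population identifiers (beads excluded).
#' @export
cyto_populations <- function() {
  c("neutrophil", "eosinophil", "classical_mono", "intermediate_mono",
    "nonclassical_mono", "activated_monomac", "lymphocyte")
}

#' Monocyte subsets of the MHC-II-negative compartment
#' @return Character vector: classical, intermediate, non-classical.
#' @export
mono_subsets <- function() c("classical_mono", "intermediate_mono", "nonclassical_mono")

cyto_labels <- function() c("bead", cyto_populations(), "ungated")

#' Default per-population channel templates
#'
#' Each template holds the median intensity (arbitrary units, true/uncompensated
#' by spillover, i.e. pre-mixing scale) and a robust CV of the log-normal
#' intensity distribution for every channel. Medians encode the phenotype
#' hierarchy: Ly6C classical > intermediate > non-classical; CD43 in the
#' reverse order; F4/80 rising from classical/intermediate through
#' non-classical to the MHC-II-positive activated subset (421/455/794/1350
#' a.u.); beads are bright on the CD11b carrier channel with a low,
#' tight scatter signature.
#'
#' @return Named list of templates, each with elements `median` and `cv`
#'   (named numeric vectors over the 8 panel channels).
#' @export
default_templates <- function() {
  ch <- cyto_channels()
  tpl <- function(FSC, SSC, CD43, Lin, MHCII, F480, CD11b, Ly6C, cv) {
    m <- c(FSC = FSC, SSC = SSC, CD43 = CD43, Lin = Lin, MHCII = MHCII,
           F480 = F480, CD11b = CD11b, Ly6C = Ly6C)
    list(median = m[ch], cv = cv[ch])
  }
  # channel spreads: tight on the classifier channels (Ly6C/CD43), broader
  # elsewhere; scatter moderately tight
  cv_cell <- c(FSC = 0.20, SSC = 0.20, CD43 = 0.25, Lin = 0.30, MHCII = 0.30,
               F480 = 0.30, CD11b = 0.30, Ly6C = 0.25)
  cv_bead <- c(FSC = 0.05, SSC = 0.05, CD43 = 0.05, Lin = 0.05, MHCII = 0.05,
               F480 = 0.05, CD11b = 0.05, Ly6C = 0.05)
  list(
    neutrophil        = tpl(70000, 150000,   500, 20000,    50,   80, 15000,  3000, cv_cell),
    eosinophil        = tpl(65000, 180000,   500,    50,    50, 5000, 15000,   150, cv_cell),
    classical_mono    = tpl(60000,  30000,   150,    50,    50,  421, 15000, 35000, cv_cell),
    intermediate_mono = tpl(60000,  30000,  2500,    50,    50,  455, 15000,  2500, cv_cell),
    nonclassical_mono = tpl(60000,  30000, 35000,    50,    50,  794, 15000,   150, cv_cell),
    activated_monomac = tpl(60000,  30000, 35000,    50, 10000, 1350, 15000,   150, cv_cell),
    lymphocyte        = tpl(45000,  20000,   500, 20000,   500,   50,    50,   150, cv_cell),
    bead              = tpl(10000,   2000,   100,   100,   100,  100, 200000,  100, cv_bead)
  )
}

#' Default spillover matrix for the six-colour panel
#'
#' Entry (i, j) is the fraction of channel-i signal appearing in channel j;
#' diagonal is 1. Off-diagonals model the usual leak pairs of this fluorochrome
#' set (FITC into PE, PE into PE-Cy7, APC/AF700 cross-talk, Pacific Blue into
#' FITC). Scatter channels are never part of the matrix.
#'
#' @return 6 x 6 numeric matrix with dimnames over the fluorescence channels.
#' @export
default_spillover <- function() {
  fl <- cyto_fluor_channels()
  S <- diag(length(fl))
  dimnames(S) <- list(fl, fl)
  S["CD43", "Lin"]    <- 0.12
  S["CD43", "MHCII"]  <- 0.01
  S["Lin", "CD43"]    <- 0.02
  S["Lin", "MHCII"]   <- 0.08
  S["MHCII", "Lin"]   <- 0.01
  S["MHCII", "CD11b"] <- 0.02
  S["F480", "CD11b"]  <- 0.10
  S["CD11b", "F480"]  <- 0.06
  S["Ly6C", "CD43"]   <- 0.02
  S
}

check_templates <- function(templates) {
  ch <- cyto_channels()
  for (nm in names(templates)) {
    t <- templates[[nm]]
    if (!all(ch %in% names(t$median)) || !all(ch %in% names(t$cv)))
      stopf("template '%s' must define median and cv for all panel channels", nm)
    if (any(t$median <= 0)) stopf("template '%s': medians must be > 0", nm)
    if (any(t$cv < 0)) stopf("template '%s': spreads must be >= 0", nm)
  }
  # phenotype ordering invariants
  g <- function(p, chn) templates[[p]]$median[[chn]]
  if (!(g("classical_mono", "Ly6C") > g("intermediate_mono", "Ly6C") &&
        g("intermediate_mono", "Ly6C") > g("nonclassical_mono", "Ly6C")))
    stopf("Ly6C medians must be ordered classical > intermediate > non-classical")
  if (!(g("nonclassical_mono", "CD43") > g("intermediate_mono", "CD43") &&
        g("intermediate_mono", "CD43") > g("classical_mono", "CD43")))
    stopf("CD43 medians must be ordered non-classical > intermediate > classical")
  if (!(g("activated_monomac", "F480") > g("nonclassical_mono", "F480") &&
        g("nonclassical_mono", "F480") > g("classical_mono", "F480")))
    stopf("F4/80 medians must be ordered activated > non-classical > classical")
  invisible(templates)
}
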