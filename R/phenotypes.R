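## Phenotype gates over marker-positivity columns.
##
## Gating hierarchy (a declared convention; phenotyping software emits
## mutually exclusive classes): CK positivity dominates, so CK+ cells are
## tumor cells and are excluded from every T-cell gate; within CK- cells the
## CD4 and CD8 lineages are exclusive, and CD4+CD8+ double positives belong
## to neither ("other"). Treg = FOXP3+ within a lineage, Tcon = FOXP3-.

#' Marker sets of the two mIF panels
#'
#' Panel 1 phenotypes T-cell subsets (CK, CD4, CD8, FOXP3); panel 2 targets
#' the PD-1/PD-L1 axis (CK, FOXP3, PD1, PDL1).
#'
#' @param panel `"panel1"` or `"panel2"`.
#' @return Character vector of marker column names.
#' @examples
#' panelMarkers("panel1")
#' @export
panelMarkers <- function(panel = c("panel1", "panel2")) {
  panel <- match.arg(panel)
  switch(panel,
    panel1 = c("CK", "CD4", "CD8", "FOXP3"),
    panel2 = c("CK", "FOXP3", "PD1", "PDL1"))
}

## gate definitions: markers needed, and a predicate over a logical data.frame
.PHENOTYPE_GATES <- list(
  Tumor    = list(markers = "CK",
                  gate = function(m) m$CK),
  CD4all   = list(markers = c("CK", "CD4", "CD8"),
                  gate = function(m) !m$CK & m$CD4 & !m$CD8),
  CD8all   = list(markers = c("CK", "CD4", "CD8"),
                  gate = function(m) !m$CK & !m$CD4 & m$CD8),
  CD4Treg  = list(markers = c("CK", "CD4", "CD8", "FOXP3"),
                  gate = function(m) !m$CK & m$CD4 & !m$CD8 & m$FOXP3),
  CD4Tcon  = list(markers = c("CK", "CD4", "CD8", "FOXP3"),
                  gate = function(m) !m$CK & m$CD4 & !m$CD8 & !m$FOXP3),
  CD8Treg  = list(markers = c("CK", "CD4", "CD8", "FOXP3"),
                  gate = function(m) !m$CK & !m$CD4 & m$CD8 & m$FOXP3),
  CD8Tcon  = list(markers = c("CK", "CD4", "CD8", "FOXP3"),
                  gate = function(m) !m$CK & !m$CD4 & m$CD8 & !m$FOXP3),
  FOXP3pos = list(markers = "FOXP3",
                  gate = function(m) m$FOXP3),
  PD1pos   = list(markers = "PD1",
                  gate = function(m) m$PD1),
  PDL1pos  = list(markers = "PDL1",
                  gate = function(m) m$PDL1)
)

#' Supported cell phenotypes
#'
#' Phenotypes gated from marker positivity. `CD4all`/`CD8all` are whole
#' lineages (CK- single-positive T cells, Tregs included); `CD4Treg` etc.
#' split each lineage by FOXP3. `Tumor` is any CK+ cell.
#'
#' @return Character vector of phenotype names.
#' @export
phenotypeNames <- function() names(.PHENOTYPE_GATES)

.checkPhenotype <- function(phenotype) {
  if (!is.character(phenotype) || length(phenotype) != 1L ||
      !phenotype %in% names(.PHENOTYPE_GATES))
    stop("unknown phenotype '", paste(phenotype, collapse = ","),
         "'; see phenotypeNames()", call. = FALSE)
  .PHENOTYPE_GATES[[phenotype]]
}

#' Gate cells of a phenotype
#'
#' Returns the rows of a cell table (or the cells of a [CellCore]) whose
#' marker combination satisfies the phenotype gate. CK+ cells are never
#' returned by a T-cell gate.
#'
#' @param x A [CellCore] or a data.frame with logical/0-1 marker columns.
#' @param phenotype A phenotype name from [phenotypeNames()].
#' @return For `gatePhenotype`, the gated subset (same class of table);
#'   for `gateMask`, a logical vector over rows.
#' @examples
#' cells <- data.frame(CK = c(TRUE, FALSE), CD4 = c(FALSE, TRUE),
#'                     CD8 = FALSE, FOXP3 = c(FALSE, TRUE))
#' gateMask(cells, "CD4Treg")
#' @export
gateMask <- function(x, phenotype) {
  def <- .checkPhenotype(phenotype)
  cells <- if (is(x, "CellCore")) cells(x) else x
  missing <- setdiff(def$markers, colnames(cells))
  if (length(missing))
    stop("phenotype '", phenotype, "' requires marker(s) ",
         paste(missing, collapse = ", "), " absent from this panel",
         call. = FALSE)
  m <- as.data.frame(lapply(cells[def$markers], function(v) as.logical(v)))
  names(m) <- def$markers
  mask <- def$gate(m)
  mask & !is.na(mask)
}

#' @rdname gateMask
#' @export
gatePhenotype <- function(x, phenotype) {
  cells <- if (is(x, "CellCore")) cells(x) else x
  cells[gateMask(x, phenotype), , drop = FALSE]
}

#' Count cells per phenotype
#'
#' @param x A [CellCore] or cell data.frame.
#' @param phenotypes Phenotype names (default: all gates evaluable on the
#'   available marker columns).
#' @return Named integer vector of counts.
#' @export
phenotypeCounts <- function(x, phenotypes = NULL) {
  cells <- if (is(x, "CellCore")) cells(x) else x
  if (is.null(phenotypes)) {
    phenotypes <- names(Filter(
      function(def) all(def$markers %in% colnames(cells)), .PHENOTYPE_GATES))
  }
  vapply(phenotypes, function(p) sum(gateMask(x, p)), integer(1))
}

## markers switched on for a simulated cell of each phenotype
.PHENOTYPE_MARKER_ON <- list(
  Tumor = "CK", CD4all = "CD4", CD8all = "CD8",
  CD4Treg = c("CD4", "FOXP3"), CD4Tcon = "CD4",
  CD8Treg = c("CD8", "FOXP3"), CD8Tcon = "CD8",
  FOXP3pos = "FOXP3", PD1pos = "PD1", PDL1pos = "PDL1"
)
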