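# The wristband PAH panel: 62 target analytes with default instrumental LODs.

PAH_PANEL_NAMES <- c(
  "naphthalene", "1-methylnaphthalene", "2-methylnaphthalene",
  "1-ethylnaphthalene", "2-ethylnaphthalene",
  "1,2-dimethylnaphthalene", "1,3-dimethylnaphthalene",
  "1,4-dimethylnaphthalene", "1,5-dimethylnaphthalene",
  "1,6-dimethylnaphthalene", "1,8-dimethylnaphthalene",
  "2,6-dimethylnaphthalene", "2,7-dimethylnaphthalene",
  "1,6,7-trimethylnaphthalene", "2,3,5-trimethylnaphthalene",
  "2,3,6-trimethylnaphthalene", "1,4,6,7-tetramethylnaphthalene",
  "acenaphthylene", "acenaphthene", "fluorene", "1-methylfluorene",
  "dibenzothiophene", "phenanthrene", "anthracene",
  "1-methylphenanthrene", "2-methylphenanthrene", "3-methylphenanthrene",
  "2-methylanthracene", "9-methylanthracene",
  "3,6-dimethylphenanthrene", "2,3-dimethylanthracene",
  "9,10-dimethylanthracene", "retene", "4H-cyclopenta[def]phenanthrene",
  "fluoranthene", "pyrene", "1-methylpyrene",
  "benzo[a]fluorene", "benzo[b]fluorene", "benzo[c]fluorene",
  "benzo[ghi]fluoranthene", "benz[a]anthracene", "chrysene",
  "triphenylene", "1-methylchrysene", "6-methylchrysene",
  "benzo[b]fluoranthene", "benzo[j]fluoranthene", "benzo[k]fluoranthene",
  "benzo[e]pyrene", "benzo[a]pyrene", "perylene",
  "indeno[1,2,3-cd]pyrene", "dibenz[a,h]anthracene", "benzo[ghi]perylene",
  "anthanthrene", "coronene", "picene",
  "dibenzo[a,l]pyrene", "dibenzo[a,e]pyrene", "dibenzo[a,i]pyrene",
  "dibenzo[a,h]pyrene"
)

# Names whose presence the panel registry guarantees: the analytes detected in
# every wristband of the feasibility cohort.
PAH_CORE_NAMES <- c(
  "phenanthrene", "2-methylnaphthalene", "1,6-dimethylnaphthalene",
  "naphthalene", "2,6-dimethylnaphthalene", "fluorene",
  "1-methylnaphthalene", "2-ethylnaphthalene", "dibenzothiophene"
)

#' The 62-analyte PAH panel registry
#'
#' Returns the target-analyte registry used by the wristband module: one row
#' per analyte with a default instrumental limit of detection (ng/wristband).
#' Default LODs decrease with molecular weight, mirroring typical GC-MS/MS
#' sensitivity. Nine always-detected analytes (phenanthrene,
#' 2-methylnaphthalene, 1,6-dimethylnaphthalene, naphthalene,
#' 2,6-dimethylnaphthalene, fluorene, 1-methylnaphthalene,
#' 2-ethylnaphthalene, dibenzothiophene) are guaranteed present; the rest of
#' the panel may be replaced via `extra`.
#'
#' @param extra Optional character vector of analyte names replacing the
#'   non-core panel entries (the panel is padded/truncated back to `n`).
#' @param n Panel size (default 62).
#' @return A tibble with columns `analyte` and `lod`.
#' @export
pah_panel <- function(extra = NULL, n = 62L) {
  names <- PAH_PANEL_NAMES
  if (!is.null(extra)) {
    names <- unique(c(PAH_CORE_NAMES, extra))
    if (length(names) < n) {
      names <- c(names, setdiff(PAH_PANEL_NAMES, names))
    }
    names <- names[seq_len(min(n, length(names)))]
  }
  if (anyDuplicated(names)) stop("panel analyte names must be unique", call. = FALSE)
  if (!all(PAH_CORE_NAMES %in% names)) {
    stop("panel must contain the nine core analytes", call. = FALSE)
  }
  idx <- seq_along(names)
  lod <- c(5, 2, 1, 0.5)[pmin(4, 1L + (idx - 1L) %/% 16L)]
  tibble::tibble(analyte = names, lod = lod)
}
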