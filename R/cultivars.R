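#' Maize cultivar coefficients
#'
#' The six genotype-specific parameters driving phenology and yield
#' formation: `P1` (thermal time from seedling emergence to the end of the
#' juvenile phase, deg C d), `P2` (days of development delay per hour that
#' day length exceeds 12.5 h), `P5` (thermal time from silking to
#' physiological maturity, deg C d), `G2` (maximum kernels per plant), `G3`
#' (kernel growth rate during linear grain fill, mg/day), and `PHINT`
#' (phyllochron interval: thermal time between successive leaf-tip
#' appearances, deg C d).
#'
#' `maize_cultivars()` returns the packaged set of 16 calibrated Nigerian
#' savanna varieties spanning four maturity groups (extra-early, early,
#' intermediate, late); `read_cultivars()` reads the same CSV dialect
#' (`name,P1,P2,P5,G2,G3,PHINT`, optional `maturity_group`) from a file.
#'
#' @param path Path to a cultivar coefficient CSV.
#' @return A tibble with columns `name`, `maturity_group` (if present),
#'   `P1`, `P2`, `P5`, `G2`, `G3`, `PHINT`.
#' @examples
#' maize_cultivars()
#' @export
maize_cultivars <- function() {
  read_cultivars(system.file("extdata", "cultivars_table2.csv",
                             package = "gxemaize", mustWork = TRUE))
}

#' @rdname maize_cultivars
#' @export
read_cultivars <- function(path) {
  cv <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("name", "P1", "P2", "P5", "G2", "G3", "PHINT")
  if (!all(need %in% names(cv))) {
    abort(paste0("Cultivar file must have columns ",
                 paste(need, collapse = ", ")))
  }
  validate_cultivar(cv)
  tibble::as_tibble(cv)
}

validate_cultivar <- function(cv) {
  with(cv, {
    if (any(P1 < 150 | P1 > 350)) abort("P1 out of plausible range [150, 350].")
    if (any(P2 < 0)) abort("P2 must be >= 0.")
    if (any(P5 <= 0 | G2 <= 0 | G3 <= 0)) {
      abort("P5, G2 and G3 must be strictly positive.")
    }
    if (any(PHINT < 30 | PHINT > 55)) {
      abort("PHINT out of plausible range [30, 55].")
    }
  })
  invisible(cv)
}

# coerce a one-row data frame / list to a cultivar list
as_cultivar <- function(cv) {
  if (is.data.frame(cv)) {
    if (nrow(cv) != 1) abort("Pass exactly one cultivar (one row).")
    cv <- as.list(cv)
  }
  need <- c("P1", "P2", "P5", "G2", "G3", "PHINT")
  if (!all(need %in% names(cv))) {
    abort(paste0("A cultivar needs fields ", paste(need, collapse = ", ")))
  }
  cv$name <- cv$name %||% "unnamed"
  cv
}
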