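#' Load the packaged phylotype panel
#'
#' The panel encodes, one row per phylotype, the generative parameters of the
#' study population: isolate counts in the pilot and main study arms, modal
#' major and minor ISR amplicon sizes with their observed ranges (bp), modal
#' acid and H2O2 scores on the 0-3 chromogenic scales (adjacent ties written
#' "a-b"), the number of double-strong isolates, a Gram morphotype
#' annotation, and for linked dual-peak organisms (Gardnerella-style wobble)
#' the fixed major-minor interval that all isolates of the phylotype
#' maintain. One phylotype has no recorded ISR sizes; its major is NA and
#' its isolates are generated as trace failures.
#'
#' @param path optional path to a panel TSV; defaults to the packaged file.
#' @return a data.frame with one row per phylotype and a `minor_modes`
#'   list-column of integer vectors (`minor_lo`/`minor_hi` likewise).
#' @export
#' @examples
#' panel <- load_phylotype_panel()
#' nrow(panel)
#' sum(panel$n_pilot + panel$n_main)
load_phylotype_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "phylotype_panel.tsv", package = "isrtyper")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stopf("phylotype panel file not found: '%s'", path)
  }
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- c("name", "genus", "named_species", "n_pilot", "n_main",
              "major_mode", "major_lo", "major_hi",
              "minor_modes", "minor_lo", "minor_hi",
              "linked_wobble", "link_interval_bp",
              "acid_mode", "h2o2_mode", "double_strong_n", "gram",
              "percent_identity_mode")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0L) {
    stopf("phylotype panel '%s' is corrupted: missing column(s) %s",
          path, paste(missing, collapse = ", "))
  }
  panel <- data.frame(
    name = raw$name,
    genus = raw$genus,
    named_species = as.logical(raw$named_species),
    n_pilot = as.integer(raw$n_pilot),
    n_main = as.integer(raw$n_main),
    major_mode = suppressWarnings(as.integer(raw$major_mode)),
    major_lo = suppressWarnings(as.integer(raw$major_lo)),
    major_hi = suppressWarnings(as.integer(raw$major_hi)),
    linked_wobble = as.logical(raw$linked_wobble),
    link_interval_bp = suppressWarnings(as.integer(raw$link_interval_bp)),
    acid_mode = raw$acid_mode,
    h2o2_mode = raw$h2o2_mode,
    double_strong_n = as.integer(raw$double_strong_n),
    gram = raw$gram,
    percent_identity_mode = as.numeric(raw$percent_identity_mode),
    stringsAsFactors = FALSE
  )
  panel$minor_modes <- split_sizes(raw$minor_modes)
  panel$minor_lo <- split_sizes(raw$minor_lo)
  panel$minor_hi <- split_sizes(raw$minor_hi)
  validate_panel(panel, path)
  panel
}

validate_panel <- function(panel, path = "<panel>") {
  if (anyDuplicated(panel$name)) {
    stopf("panel '%s' has duplicated phylotype names", path)
  }
  for (i in seq_len(nrow(panel))) {
    p <- panel[i, ]
    sized <- !is.na(p$major_mode)
    if (sized) {
      if (p$major_mode < p$major_lo || p$major_mode > p$major_hi) {
        stopf("panel row '%s': major mode outside its range", p$name)
      }
      sizes <- c(p$major_lo, p$major_hi, p$minor_modes[[1]])
      if (any(sizes < 50 | sizes > 1000)) {
        stopf("panel row '%s': sizes outside the sizable 50-1000 bp window",
              p$name)
      }
      mm <- p$minor_modes[[1]]
      lo <- p$minor_lo[[1]]; hi <- p$minor_hi[[1]]
      if (length(mm) != length(lo) || length(mm) != length(hi)) {
        stopf("panel row '%s': ragged minor mode/range columns", p$name)
      }
      if (length(mm) && any(mm < lo | mm > hi)) {
        stopf("panel row '%s': minor mode outside its range", p$name)
      }
    }
    if (p$n_pilot + p$n_main < 1L) {
      stopf("panel row '%s': zero isolates", p$name)
    }
    if (!p$named_species && p$percent_identity_mode >= 97) {
      stopf("panel row '%s': novel group must have percent identity < 97",
            p$name)
    }
    if (!score_mode_valid(p$acid_mode) || !score_mode_valid(p$h2o2_mode)) {
      stopf("panel row '%s': malformed phenotype mode", p$name)
    }
  }
  invisible(panel)
}

# a score mode is "0".."3" or an adjacent tie "a-b"
score_mode_valid <- function(s) {
  grepl("^[0-3]$", s) || grepl("^[0-3]-[0-3]$", s)
}

parse_score_mode <- function(s) {
  v <- as.integer(strsplit(s, "-", fixed = TRUE)[[1]])
  sort(v)
}

#' Default internal size standard
#'
#' The 23-fragment, 50-1000 bp co-electrophoresed ladder used to convert
#' migration position to base pairs (MapMarker 1000-style fragment sizes).
#'
#' @return strictly increasing integer vector of 23 fragment sizes (bp).
#' @export
#' @examples
#' length(default_ladder())
default_ladder <- function() {
  frags <- c(50L, 75L, 100L, 125L, 150L, 200L, 250L, 300L, 350L, 400L,
             450L, 475L, 500L, 550L, 600L, 650L, 700L, 750L, 800L, 850L,
             900L, 950L, 1000L)
  stopifnot(length(frags) == 23L, !is.unsorted(frags, strictly = TRUE))
  frags
}
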