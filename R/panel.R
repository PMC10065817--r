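#' Panel definitions and sample sheets
#'
#' An nCounter panel is a table of probes with four code classes:
#' `Endogenous` (the genes of interest), `Housekeeping` (candidate reference
#' genes), `Positive` (spike-in controls at known concentrations in fM) and
#' `Negative` (background controls). Probe identity is carried by
#' `probe_id`; the same gene symbol may map to different probe IDs on
#' different panels, so all matrix bookkeeping is keyed by probe ID and
#' cross-panel operations map by gene symbol.
#'
#' @param name Panel name.
#' @param probes `data.frame` with columns `probe_id`, `gene_symbol`,
#'   `code_class` and `concentration_fM` (`NA` except for Positive probes).
#' @return A `panel_definition` object (validated `data.frame` plus name).
#' @export
panel_definition <- function(name, probes) {
  stopifnot(is.character(name), length(name) == 1L, is.data.frame(probes))
  required <- c("probe_id", "gene_symbol", "code_class")
  missing <- setdiff(required, names(probes))
  if (length(missing) > 0L)
    stop("panel probes lack column(s): ", paste(missing, collapse = ", "))
  if (is.null(probes$concentration_fM)) probes$concentration_fM <- NA_real_
  probes <- data.frame(
    probe_id = as.character(probes$probe_id),
    gene_symbol = as.character(probes$gene_symbol),
    code_class = as.character(probes$code_class),
    concentration_fM = as.numeric(probes$concentration_fM),
    stringsAsFactors = FALSE
  )
  classes <- c("Endogenous", "Housekeeping", "Positive", "Negative")
  bad <- setdiff(unique(probes$code_class), classes)
  if (length(bad) > 0L)
    stop("unknown code_class: ", paste(bad, collapse = ", "))
  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe_id in panel: ",
         paste(unique(probes$probe_id[duplicated(probes$probe_id)]),
               collapse = ", "))
  is_pos <- probes$code_class == "Positive"
  if (any(is.na(probes$concentration_fM[is_pos])))
    stop("every Positive probe needs a concentration_fM")
  if (any(!is.na(probes$concentration_fM[!is_pos])))
    stop("concentration_fM is only meaningful for Positive probes")
  if (sum(probes$code_class == "Housekeeping") < 2L)
    stop("panel needs at least 2 Housekeeping probes")
  if (sum(is_pos) < 2L ||
      anyDuplicated(probes$concentration_fM[is_pos]) > 0L)
    stop("panel needs >= 2 Positive probes with distinct concentrations")
  if (sum(probes$code_class == "Negative") < 2L)
    stop("panel needs at least 2 Negative probes")
  structure(list(name = name, probes = probes), class = "panel_definition")
}

#' @export
print.panel_definition <- function(x, ...) {
  tab <- table(factor(x$probes$code_class,
                      c("Endogenous", "Housekeeping", "Positive", "Negative")))
  cat("nCounter panel '", x$name, "': ", nrow(x$probes), " probes (",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

panel_probe_ids <- function(panel, code_class = NULL) {
  p <- panel$probes
  if (!is.null(code_class)) p <- p[p$code_class %in% code_class, , drop = FALSE]
  p$probe_id
}

#' Read or write a panel definition CSV
#'
#' The CSV carries one row per probe with columns
#' `probe_id,gene_symbol,code_class,concentration_fM`.
#'
#' @param path File path.
#' @param name Panel name (defaults to the file name).
#' @return `read_panel()` returns a `panel_definition`.
#' @export
read_panel <- function(path, name = sub("\\.csv$", "", basename(path))) {
  probes <- utils::read.csv(path, stringsAsFactors = FALSE)
  panel_definition(name, probes)
}

#' @rdname read_panel
#' @param panel A `panel_definition`.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(panel$probes, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Read or construct a sample sheet
#'
#' Sample metadata carries `sample_id`, a `diagnosis` from the closed set
#' `NoRejection`, `BLorTCMR`, `AMR`, and the contributing `center`.
#'
#' @param x A `data.frame` (or, for `read_sample_sheet`, a CSV path).
#' @return A validated `data.frame`.
#' @export
sample_sheet <- function(x) {
  stopifnot(is.data.frame(x))
  required <- c("sample_id", "diagnosis", "center")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L)
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "))
  x$sample_id <- as.character(x$sample_id)
  x$diagnosis <- as.character(x$diagnosis)
  x$center <- as.character(x$center)
  bad <- setdiff(unique(x$diagnosis), diagnosis_levels())
  if (length(bad) > 0L)
    stop("diagnosis outside {", paste(diagnosis_levels(), collapse = ", "),
         "}: ", paste(bad, collapse = ", "))
  if (anyDuplicated(x$sample_id))
    stop("duplicate sample_id in sample sheet")
  x
}

#' @rdname sample_sheet
#' @param path CSV path.
#' @export
read_sample_sheet <- function(path) {
  sample_sheet(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname sample_sheet
#' @export
diagnosis_levels <- function() c("NoRejection", "BLorTCMR", "AMR")
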