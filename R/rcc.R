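#' Lane records and RCC files
#'
#' One RCC file is the per-lane export of an nCounter run: a sectioned CSV
#' with `<Header>`, `<Sample_Attributes>`, `<Lane_Attributes>` and
#' `<Code_Summary>` blocks. A `lane_record` captures the fields the pipeline
#' needs: the sample identity, the imaging metrics (fields of view attempted
#' and counted), the binding density in spots per square micrometer, and the
#' integer count of every probe.
#'
#' @param sample_id Sample identifier.
#' @param fov_attempted,fov_counted Fields of view attempted and successfully
#'   counted (`fov_counted <= fov_attempted`).
#' @param binding_density Reporter spot density, spots/um^2.
#' @param counts Named integer vector keyed by probe_id.
#' @return A `lane_record` object.
#' @export
lane_record <- function(sample_id, fov_attempted, fov_counted,
                        binding_density, counts) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  fov_attempted <- as.integer(fov_attempted)
  fov_counted <- as.integer(fov_counted)
  if (fov_attempted < 1L) stop("fov_attempted must be positive")
  if (fov_counted < 0L || fov_counted > fov_attempted)
    stop("fov_counted must lie in [0, fov_attempted]")
  binding_density <- as.numeric(binding_density)
  if (binding_density < 0) stop("binding_density must be nonnegative")
  if (is.null(names(counts)) || anyDuplicated(names(counts)))
    stop("counts must be uniquely named by probe_id")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  structure(
    list(sample_id = sample_id, fov_attempted = fov_attempted,
         fov_counted = fov_counted, binding_density = binding_density,
         counts = stats::setNames(as.integer(counts), names(counts))),
    class = "lane_record"
  )
}

#' @export
print.lane_record <- function(x, ...) {
  cat(sprintf(
    "lane '%s': %d probes, FOV %d/%d, binding density %.3f\n",
    x$sample_id, length(x$counts), x$fov_counted, x$fov_attempted,
    x$binding_density))
  invisible(x)
}

# Split RCC lines into named sections delimited by <Tag> ... </Tag>.
rcc_sections <- function(lines) {
  open <- grep("^<[^/][^>]*>\\s*$", lines)
  sections <- list()
  for (i in open) {
    tag <- sub("^<([^>]*)>\\s*$", "\\1", lines[i])
    close <- grep(paste0("^</", tag, ">\\s*$"), lines)
    close <- close[close > i]
    if (length(close) == 0L)
      stop("RCC section <", tag, "> is never closed")
    body <- lines[seq.int(i + 1L, close[1] - 1L)]
    sections[[tag]] <- body[nzchar(trimws(body))]
  }
  sections
}

rcc_kv <- function(body) {
  parts <- strsplit(body, ",", fixed = TRUE)
  keys <- vapply(parts, `[`, "", 1L)
  vals <- vapply(parts, function(p)
    if (length(p) >= 2L) paste(p[-1L], collapse = ",") else "", "")
  stats::setNames(gsub('^"|"$', "", vals), keys)
}

#' Read an RCC lane file
#'
#' Both quoted and unquoted fields are tolerated; sections other than the
#' four standard ones are ignored. Every `Code_Summary` row becomes one
#' entry of the returned count vector, keyed by its accession (probe ID).
#'
#' @param path Path to an RCC file.
#' @return A [lane_record()].
#' @export
read_rcc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sections <- rcc_sections(lines)
  for (required in c("Header", "Sample_Attributes", "Lane_Attributes",
                     "Code_Summary")) {
    if (is.null(sections[[required]]))
      stop("RCC file ", basename(path), " lacks section <", required, ">")
  }
  sample_attr <- rcc_kv(sections$Sample_Attributes)
  lane_attr <- rcc_kv(sections$Lane_Attributes)
  cs <- sections$Code_Summary
  header <- strsplit(gsub('"', "", cs[1]), ",", fixed = TRUE)[[1]]
  need <- c("CodeClass", "Name", "Accession", "Count")
  if (!all(need %in% header))
    stop("Code_Summary header must contain ", paste(need, collapse = ","))
  rows <- strsplit(cs[-1L], ",", fixed = TRUE)
  get <- function(row, col) gsub('^"|"$', "", row[match(col, header)])
  probe_ids <- vapply(rows, get, "", col = "Accession")
  count_str <- vapply(rows, get, "", col = "Count")
  counts <- suppressWarnings(as.numeric(count_str))
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts))
  if (length(bad) > 0L)
    stop("Code_Summary row ", bad[1], ": count '", count_str[bad[1]],
         "' is not a nonnegative integer")
  lane_record(
    sample_id = unname(sample_attr[["ID"]]),
    fov_attempted = as.integer(lane_attr[["FovCount"]]),
    fov_counted = as.integer(lane_attr[["FovCounted"]]),
    binding_density = as.numeric(lane_attr[["BindingDensity"]]),
    counts = stats::setNames(as.integer(counts), probe_ids)
  )
}

#' Write a lane to an RCC file
#'
#' The emitted file uses the sectioned-CSV dialect read by [read_rcc()];
#' write followed by read is lossless on every `lane_record` field. The
#' lane's counts must cover exactly the panel's probes, whose code classes
#' and gene symbols populate the `Code_Summary` block.
#'
#' @param lane A [lane_record()].
#' @param panel The [panel_definition()] the lane was assayed with.
#' @param path Output path.
#' @export
write_rcc <- function(lane, panel, path) {
  probes <- panel$probes
  if (!setequal(names(lane$counts), probes$probe_id) ||
      length(lane$counts) != nrow(probes))
    stop("lane '", lane$sample_id,
         "' counts do not match the probes of panel '", panel$name, "'")
  counts <- lane$counts[probes$probe_id]
  name <- ifelse(probes$code_class == "Positive",
                 sprintf("%s(%g)", probes$gene_symbol,
                         probes$concentration_fM),
                 probes$gene_symbol)
  lines <- c(
    "<Header>",
    "FileVersion,3.0",
    "SoftwareVersion,4.0.0.3",
    "</Header>",
    "<Sample_Attributes>",
    paste0("ID,", lane$sample_id),
    paste0("GeneRLF,", panel$name),
    "</Sample_Attributes>",
    "<Lane_Attributes>",
    "ID,1",
    paste0("FovCount,", lane$fov_attempted),
    paste0("FovCounted,", lane$fov_counted),
    paste0("BindingDensity,", format(lane$binding_density, digits = 15)),
    "</Lane_Attributes>",
    "<Code_Summary>",
    "CodeClass,Name,Accession,Count",
    paste(probes$code_class, name, probes$probe_id, counts, sep = ","),
    "</Code_Summary>"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Assemble a raw count matrix from lanes and metadata
#'
#' Columns follow the order of the sample sheet; the order in which lanes
#' are supplied is irrelevant. Lane attributes (FOV, binding density) are
#' carried into the sample table so QC can use them.
#'
#' @param lanes List of [lane_record()]s, one per sample-sheet row.
#' @param panel A [panel_definition()].
#' @param metadata A [sample_sheet()] `data.frame`.
#' @return A `count_matrix` at stage `"raw"`.
#' @export
assemble_matrix <- function(lanes, panel, metadata) {
  metadata <- sample_sheet(metadata)
  ids <- vapply(lanes, function(l) l$sample_id, "")
  if (anyDuplicated(ids))
    stop("duplicate sample_id among lanes: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  extra <- setdiff(ids, metadata$sample_id)
  if (length(extra) > 0L)
    stop("lane(s) without sample-sheet entry: ", paste(extra, collapse = ", "))
  absent <- setdiff(metadata$sample_id, ids)
  if (length(absent) > 0L)
    stop("sample-sheet entr(ies) without lane: ",
         paste(absent, collapse = ", "))
  lanes <- lanes[match(metadata$sample_id, ids)]
  probes <- panel$probes$probe_id
  values <- vapply(lanes, function(l) {
    if (!setequal(names(l$counts), probes))
      stop("lane '", l$sample_id, "' probes do not match panel '",
           panel$name, "'")
    as.numeric(l$counts[probes])
  }, numeric(length(probes)))
  dimnames(values) <- list(probes, metadata$sample_id)
  samples <- metadata
  samples$fov_attempted <- vapply(lanes, function(l) l$fov_attempted, 1L)
  samples$fov_counted <- vapply(lanes, function(l) l$fov_counted, 1L)
  samples$binding_density <-
    vapply(lanes, function(l) l$binding_density, 1.0)
  count_matrix(panel, samples, values, stage = "raw")
}

#' Construct a count matrix
#'
#' The container every stage consumes and produces: a probes x samples
#' matrix of nonnegative values plus the panel annotation and per-sample
#' metadata, tagged with its processing stage (`raw`, `pos_normalized` or
#' `content_normalized`).
#'
#' @param panel A [panel_definition()].
#' @param samples Sample metadata `data.frame` (one row per column).
#' @param values Numeric probes x samples matrix, rows named by probe_id.
#' @param stage Processing stage tag.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(panel, samples, values,
                         stage = c("raw", "pos_normalized",
                                   "content_normalized")) {
  stage <- match.arg(stage)
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(is.na(values))) stop("count matrix must have no missing entries")
  if (any(values < 0)) stop("count matrix values must be nonnegative")
  if (stage == "raw" && any(values != round(values)))
    stop("raw-stage counts must be integers")
  if (nrow(samples) != ncol(values))
    stop("sample table and matrix columns disagree")
  if (is.null(rownames(values)))
    stop("values must have probe_id rownames")
  if (length(setdiff(rownames(values), panel$probes$probe_id)) > 0L)
    stop("matrix rows must be probes of the panel")
  colnames(values) <- samples$sample_id
  structure(list(panel = panel, samples = samples, values = values,
                 stage = stage),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix [%s]: %d probes x %d samples, panel '%s'\n",
              x$stage, nrow(x$values), ncol(x$values), x$panel$name))
  if (!is.null(x$samples$diagnosis)) {
    tab <- table(x$samples$diagnosis)
    cat("  diagnoses:",
        paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

# Rows of the matrix belonging to a code class (in panel order).
matrix_rows <- function(mat, code_class) {
  ids <- panel_probe_ids(mat$panel, code_class)
  ids[ids %in% rownames(mat$values)]
}

# Replace columns, keeping annotation consistent.
subset_samples <- function(mat, keep) {
  count_matrix(mat$panel, mat$samples[keep, , drop = FALSE],
               mat$values[, keep, drop = FALSE], stage = mat$stage)
}
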