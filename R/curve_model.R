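#' Construct a single growth curve
#'
#' A growth curve is one OD600 time series for one strain and one
#' experimental replicate, sampled on a uniform time grid (hours).
#'
#' @param strain_id Character scalar; strain (= deleted gene) name.
#' @param replicate Integer >= 1; replicate index. Metadata only, no
#'   ordering semantics.
#' @param times Numeric vector of sampling times in hours, strictly
#'   increasing with a constant step (default plate-reader cadence is
#'   0.25 h).
#' @param od Numeric vector of OD600 readings, same length as `times`,
#'   finite and non-negative.
#' @param stage Either `"raw"` or `"preprocessed"`.
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(strain_id, replicate, times, od, stage = "raw") {
  stage <- match.arg(stage, c("raw", "preprocessed"))
  if (!is.character(strain_id) || length(strain_id) != 1L || !nzchar(strain_id))
    stop("strain_id must be a non-empty character scalar")
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L)
    stop("replicate must be an integer >= 1")
  times <- as.numeric(times)
  od <- as.numeric(od)
  if (length(times) != length(od))
    stop("times and od must have the same length")
  if (length(times) < 3L)
    stop("a growth curve needs at least 3 points")
  steps <- diff(times)
  if (any(steps <= 0))
    stop("times must be strictly increasing")
  if (max(steps) - min(steps) > 1e-6)
    stop(sprintf("non-uniform time step in curve %s:%d (range %.3g to %.3g h)",
                 strain_id, replicate, min(steps), max(steps)))
  if (any(!is.finite(od)) || any(od < 0))
    stop(sprintf("od values must be finite and >= 0 (curve %s:%d)",
                 strain_id, replicate))
  structure(
    list(strain_id = strain_id, replicate = replicate,
         times = times, od = od, stage = stage),
    class = "growth_curve"
  )
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> %s:%d  %d points, %.2f-%.2f h, OD %.3f-%.3f [%s]\n",
              x$strain_id, x$replicate, length(x$od),
              min(x$times), max(x$times), min(x$od), max(x$od), x$stage))
  invisible(x)
}

#' Curve identifier
#'
#' The canonical id of a curve is `"strain:replicate"`.
#'
#' @param curve A `growth_curve`.
#' @return Character scalar.
#' @export
curve_id <- function(curve) paste0(curve$strain_id, ":", curve$replicate)

#' Assemble curves into a collection grouped by strain
#'
#' @param curves List of [growth_curve()] objects. Duplicate
#'   strain/replicate combinations are rejected.
#' @return An object of class `curve_collection` with elements `curves`
#'   (the list) and `groups` (named list mapping strain id to the integer
#'   indices of its replicate curves). Every curve belongs to exactly one
#'   group.
#' @export
curve_collection <- function(curves) {
  if (!is.list(curves)) stop("curves must be a list")
  if (length(curves) > 0 && !all(vapply(curves, inherits, logical(1), "growth_curve")))
    stop("all elements must be growth_curve objects")
  ids <- vapply(curves, curve_id, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate curve id: %s", ids[duplicated(ids)][1]))
  strains <- vapply(curves, function(c) c$strain_id, character(1))
  groups <- split(seq_along(curves), factor(strains, levels = unique(strains)))
  structure(list(curves = curves, groups = groups), class = "curve_collection")
}

#' @export
print.curve_collection <- function(x, ...) {
  sizes <- lengths(x$groups)
  cat(sprintf("<curve_collection> %d curves, %d strains (group sizes %s)\n",
              length(x$curves), length(x$groups),
              paste(range(if (length(sizes)) sizes else 0), collapse = "-")))
  invisible(x)
}

#' @export
length.curve_collection <- function(x) length(x$curves)

#' Curve ids of a collection
#' @param collection A `curve_collection`.
#' @return Character vector of `"strain:replicate"` ids.
#' @export
curve_ids <- function(collection) {
  vapply(collection$curves, curve_id, character(1))
}

.infer_sep <- function(path) {
  if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read growth curves from a delimited table
#'
#' Two dialects are supported. `wide`: first column is time, remaining
#' columns are named `"strain:replicate"`; trailing `NA` cells let curves
#' of different lengths share one file. `long`: columns `strain`,
#' `replicate`, `time`, `od`. Separator is inferred from the extension
#' (`.tsv`/`.tab`/`.txt` = tab, otherwise comma).
#'
#' @param path File path.
#' @param layout `"wide"` or `"long"`.
#' @param time_unit `"hours"` (default) or `"minutes"`; minutes are
#'   converted to hours on read.
#' @param sep Field separator; overrides extension-based inference.
#' @return A validated [curve_collection()] with stage `"raw"`.
#' @export
read_curves <- function(path, layout = c("wide", "long"),
                        time_unit = c("hours", "minutes"), sep = NULL) {
  layout <- match.arg(layout)
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(sep)) sep <- .infer_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  tconv <- if (time_unit == "minutes") 1 / 60 else 1

  if (layout == "wide") {
    if (ncol(df) < 2) stop("wide layout needs a time column plus at least one curve column")
    times <- suppressWarnings(as.numeric(df[[1]]))
    if (any(is.na(times))) stop(sprintf("non-numeric time value at row %d",
                                        which(is.na(times))[1]))
    times <- times * tconv
    steps <- diff(times)
    if (any(steps <= 0) || max(steps) - min(steps) > 1e-6) {
      bad <- which(abs(steps - steps[1]) > 1e-6 | steps <= 0)[1] + 1L
      stop(sprintf("non-uniform time step at row %d of the time column", bad))
    }
    curves <- vector("list", ncol(df) - 1L)
    for (ci in seq(2L, ncol(df))) {
      nm <- colnames(df)[ci]
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2L)
        stop(sprintf("malformed header '%s': expected 'strain:replicate'", nm))
      od <- suppressWarnings(as.numeric(df[[ci]]))
      present <- !is.na(df[[ci]])
      if (any(is.na(od) & present))
        stop(sprintf("non-numeric OD in column '%s' row %d", nm,
                     which(is.na(od) & present)[1]))
      keep <- !is.na(od)
      if (any(keep) && any(!keep[seq_len(max(which(keep)))]))
        stop(sprintf("interior NA in column '%s': only trailing padding is allowed", nm))
      curves[[ci - 1L]] <- growth_curve(parts[1], as.integer(parts[2]),
                                        times[keep], od[keep])
    }
    return(curve_collection(curves))
  }

  need <- c("strain", "replicate", "time", "od")
  if (!all(need %in% colnames(df)))
    stop(sprintf("long layout needs columns %s", paste(need, collapse = ", ")))
  df$time <- suppressWarnings(as.numeric(df$time)) * tconv
  df$od <- suppressWarnings(as.numeric(df$od))
  if (any(is.na(df$time))) stop("non-numeric time value in long table")
  if (any(is.na(df$od))) stop(sprintf("non-numeric OD at row %d", which(is.na(df$od))[1]))
  key <- paste(df$strain, df$replicate, sep = ":")
  curves <- lapply(unique(key), function(k) {
    sub <- df[key == k, , drop = FALSE]
    sub <- sub[order(sub$time), , drop = FALSE]
    growth_curve(sub$strain[1], as.integer(sub$replicate[1]), sub$time, sub$od)
  })
  curve_collection(curves)
}

#' Write growth curves to a delimited table
#'
#' Inverse of [read_curves()]: numeric content round-trips to 1e-9. In the
#' wide layout all curves must share the same time origin and step; shorter
#' curves are padded with empty cells.
#'
#' @param collection A `curve_collection`.
#' @inheritParams read_curves
#' @return Invisibly, `path`.
#' @export
write_curves <- function(collection, path, layout = c("wide", "long"), sep = NULL) {
  layout <- match.arg(layout)
  if (is.null(sep)) sep <- .infer_sep(path)
  if (layout == "long") {
    rows <- lapply(collection$curves, function(c)
      data.frame(strain = c$strain_id, replicate = c$replicate,
                 time = c$times, od = c$od, stringsAsFactors = FALSE))
    df <- if (length(rows)) do.call(rbind, rows)
          else data.frame(strain = character(), replicate = integer(),
                          time = numeric(), od = numeric())
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  if (length(collection$curves) == 0) {
    writeLines("time", path)
    return(invisible(path))
  }
  lens <- vapply(collection$curves, function(c) length(c$times), integer(1))
  longest <- collection$curves[[which.max(lens)]]
  t0 <- vapply(collection$curves, function(c) c$times[1], numeric(1))
  st <- vapply(collection$curves, function(c) c$times[2] - c$times[1], numeric(1))
  if (max(t0) - min(t0) > 1e-9 || max(st) - min(st) > 1e-9)
    stop("wide layout requires all curves to share time origin and step; use layout='long'")
  grid <- longest$times
  mat <- matrix(NA_real_, nrow = length(grid), ncol = length(collection$curves))
  for (i in seq_along(collection$curves))
    mat[seq_len(lens[i]), i] <- collection$curves[[i]]$od
  df <- data.frame(time = grid, mat, check.names = FALSE)
  colnames(df) <- c("time", curve_ids(collection))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Construct an annotation map
#'
#' Maps each gene (= knockout strain id) to the set of functional
#' categories it belongs to; category sizes are counted over the map's own
#' gene universe, each gene counted once per category.
#'
#' @param gene_to_categories Named list: gene id -> character vector of
#'   category labels.
#' @return Object of class `annotation_map` with `gene_to_categories` and
#'   `category_sizes`.
#' @export
annotation_map <- function(gene_to_categories) {
  if (length(gene_to_categories) && is.null(names(gene_to_categories)))
    stop("gene_to_categories must be a named list")
  gene_to_categories <- lapply(gene_to_categories, function(x) {
    x <- unique(as.character(x))
    if (any(!nzchar(x))) stop("empty category label")
    x
  })
  tab <- table(unlist(gene_to_categories, use.names = FALSE))
  sizes <- stats::setNames(as.integer(tab), names(tab))
  structure(list(gene_to_categories = gene_to_categories,
                 category_sizes = sizes),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("<annotation_map> %d genes, %d categories\n",
              length(x$gene_to_categories), length(x$category_sizes)))
  invisible(x)
}

#' Read a gene-to-category annotation table
#'
#' Two-column TSV (`gene`, `category`), one row per assignment; a header
#' row named exactly `gene`/`category` is detected and skipped; duplicate
#' rows collapse.
#'
#' @param path File path.
#' @return An [annotation_map()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          col.names = c("gene", "category"),
                          colClasses = "character")
  if (nrow(df) == 0) stop("empty annotation file")
  if (identical(tolower(unlist(df[1, ], use.names = FALSE)), c("gene", "category")))
    df <- df[-1, , drop = FALSE]
  if (nrow(df) == 0) stop("annotation file has a header but no rows")
  if (any(!nzchar(df$category)))
    stop(sprintf("empty category for gene '%s'", df$gene[!nzchar(df$category)][1]))
  annotation_map(split(df$category, df$gene))
}

#' Write an annotation map as a two-column TSV
#' @param annotations An [annotation_map()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(annotations, path) {
  g <- annotations$gene_to_categories
  df <- data.frame(gene = rep(names(g), lengths(g)),
                   category = unlist(g, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
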