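#' Read a gene-by-sample FPKM expression matrix
#'
#' Reads a tab-separated expression table (first column gene identifiers,
#' header row of sample identifiers, FPKM values) and validates it: all
#' values must be finite, non-negative numbers, and gene and sample
#' identifiers must be unique. Missing values are not permitted — upstream
#' quantifiers emit 0, not NA, so an NA token indicates a corrupt table.
#'
#' @param path Path to a tab-separated text file.
#' @return A numeric matrix, genes as rows (rownames) and samples as
#'   columns (colnames), in the input order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(c(1, 0, 12.5, 3, 8, 0.2), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' write_table(m, tf)
#' read_expression_matrix(tf)
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop_ss("expression table needs a gene-id column plus >=1 sample column")
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(gene_ids))
    stop_ss("duplicate gene ids: ",
            paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop_ss("duplicate sample ids: ",
            paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(gene_ids, sample_ids))
  bad <- which(is.na(vals) | !is.finite(vals) | vals < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    r <- bad[1L, 1L]; c <- bad[1L, 2L]
    stop_ss("invalid expression value '", df[r, c + 1L], "' at gene '",
            gene_ids[r], "', sample '", sample_ids[c],
            "' (values must be finite, non-negative, non-missing)")
  }
  validate_expression_matrix(vals)
}

validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_ss("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_ss("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(x))) stop_ss("duplicate gene ids")
  if (anyDuplicated(colnames(x))) stop_ss("duplicate sample ids")
  if (any(!is.finite(x)) || any(x < 0))
    stop_ss("expression values must be finite and >= 0")
  x
}

#' Read a sample metadata table
#'
#' Required columns: `sample_id`, `condition`, `stage`, `diurnal_phase`
#' (light/dark), `growth_phase` (early/late), `replicate`; optional `time`
#' (hours). Categorical labels are normalized to lower case. The tuple
#' (condition, stage, diurnal_phase, growth_phase, replicate) must identify
#' each sample uniquely.
#'
#' @param path Path to a tab-separated text file with a header row.
#' @return A data.frame of validated metadata records.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_metadata(df)
}

validate_sample_metadata <- function(df) {
  required <- c("sample_id", "condition", "stage", "diurnal_phase",
                "growth_phase", "replicate")
  missing <- setdiff(required, colnames(df))
  if (length(missing) > 0L)
    stop_ss("metadata is missing required column(s): ",
            paste(missing, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$condition <- as.character(df$condition)
  df$replicate <- as.character(df$replicate)
  df$diurnal_phase <- tolower(as.character(df$diurnal_phase))
  df$growth_phase <- tolower(as.character(df$growth_phase))
  df$stage <- as.integer(df$stage)
  if (any(is.na(df$stage)) || any(df$stage < 1L))
    stop_ss("stage must be a positive integer")
  bad_d <- setdiff(unique(df$diurnal_phase), c("light", "dark"))
  if (length(bad_d) > 0L)
    stop_ss("unknown diurnal_phase label(s): ", paste(bad_d, collapse = ", "),
            " (allowed: light, dark)")
  bad_g <- setdiff(unique(df$growth_phase), c("early", "late"))
  if (length(bad_g) > 0L)
    stop_ss("unknown growth_phase label(s): ", paste(bad_g, collapse = ", "),
            " (allowed: early, late)")
  if (anyDuplicated(df$sample_id))
    stop_ss("duplicate sample_id in metadata")
  key <- interaction(df$condition, df$stage, df$diurnal_phase,
                     df$growth_phase, df$replicate, drop = TRUE)
  if (anyDuplicated(key))
    stop_ss("(condition, stage, diurnal_phase, growth_phase, replicate) ",
            "does not uniquely identify samples")
  if ("time" %in% colnames(df)) df$time <- as.numeric(df$time)
  df
}

#' Write a pipeline table deterministically
#'
#' Writes matrices and data.frames as tab-separated text with a fixed
#' column order and fixed numeric rendering (15 significant digits), so
#' repeated calls on the same object produce byte-identical files.
#'
#' @param object A numeric matrix (written with an `id` first column from
#'   its rownames) or a data.frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(object, path) {
  fmt <- function(x) {
    if (is.double(x)) sprintf("%.15g", x) else as.character(x)
  }
  if (is.matrix(object)) {
    df <- data.frame(id = rownames(object),
                     apply(object, 2L, fmt),
                     check.names = FALSE, stringsAsFactors = FALSE)
  } else if (is.data.frame(object)) {
    df <- as.data.frame(lapply(object, fmt), check.names = FALSE,
                        stringsAsFactors = FALSE)
    colnames(df) <- colnames(object)
  } else {
    stop_ss("write_table handles matrices and data.frames")
  }
  con <- file(path, open = "wb")  # binary: fixed \n line endings
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Cross-check an expression matrix against sample metadata
#'
#' Report-only validation: lists samples missing metadata, metadata rows
#' without a matching expression column, and, per (condition, stage), which
#' of the four diurnal-by-growth label combinations are absent.
#'
#' @param expr Expression matrix (genes x samples).
#' @param meta Metadata data.frame (see [read_sample_metadata()]).
#' @param strict If TRUE, any finding is escalated to an error.
#' @return A data.frame of findings with columns `type` and `detail`;
#'   zero rows when the dataset is fully consistent.
#' @export
validate_dataset <- function(expr, meta, strict = FALSE) {
  expr <- validate_expression_matrix(expr)
  meta <- validate_sample_metadata(meta)
  findings <- list()
  no_meta <- setdiff(colnames(expr), meta$sample_id)
  for (s in no_meta)
    findings[[length(findings) + 1L]] <-
      c("missing_metadata", paste0("sample '", s, "' has no metadata row"))
  no_expr <- setdiff(meta$sample_id, colnames(expr))
  for (s in no_expr)
    findings[[length(findings) + 1L]] <-
      c("unmatched_metadata", paste0("metadata sample '", s,
                                     "' has no expression column"))
  combos <- expand.grid(diurnal_phase = c("light", "dark"),
                        growth_phase = c("early", "late"),
                        stringsAsFactors = FALSE)
  for (cond in unique(meta$condition)) {
    for (st in unique(meta$stage[meta$condition == cond])) {
      sub <- meta[meta$condition == cond & meta$stage == st, ]
      have <- paste(sub$diurnal_phase, sub$growth_phase)
      miss <- combos[!paste(combos$diurnal_phase, combos$growth_phase)
                     %in% have, , drop = FALSE]
      for (k in seq_len(nrow(miss)))
        findings[[length(findings) + 1L]] <-
          c("coverage", paste0("condition '", cond, "' stage ", st,
                               " lacks (", miss$diurnal_phase[k], ", ",
                               miss$growth_phase[k], ") samples"))
    }
  }
  rep <- if (length(findings) == 0L) {
    data.frame(type = character(), detail = character(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(type = vapply(findings, `[`, "", 1L),
               detail = vapply(findings, `[`, "", 2L),
               stringsAsFactors = FALSE)
  }
  if (strict && nrow(rep) > 0L)
    stop_ss("dataset validation failed:\n  ",
            paste(rep$detail, collapse = "\n  "))
  rep
}
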