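# internal helpers: validation, seeding, logging

SCFA_ACIDS <- c("acetate", "propionate", "butyrate")
SCFA_TYPES <- c(SCFA_ACIDS, "total")

assert_scalar_number <- function(x, field, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", field))
  }
  if (x < min) {
    abort(sprintf("`%s` must be >= %s (got %s).", field, min, x))
  }
  invisible(x)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "%s is missing required column(s): %s.",
      what, paste(missing, collapse = ", ")
    ), class = "fibersynergy_schema_error")
  }
  invisible(df)
}

# run `expr` under a seed when one is given, leaving the global RNG alone
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# deterministic per-stage seed derived from a global one; stays inside
# 32-bit integer range for any |seed| < ~2.1e6
derive_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 1009 + stage_index * 97) %% .Machine$integer.max)
}

# coerce a taxa table (tibble with taxon-id first column, or matrix with
# rownames) to an integer matrix of taxa x samples
taxa_matrix <- function(counts) {
  if (is.matrix(counts)) {
    if (is.null(rownames(counts))) {
      abort("taxa count matrix must have taxon ids as rownames.")
    }
    m <- counts
  } else {
    counts <- as.data.frame(counts)
    if (ncol(counts) < 2L) abort("taxa count table has no sample columns.")
    m <- as.matrix(counts[, -1, drop = FALSE])
    rownames(m) <- as.character(counts[[1]])
  }
  if (nrow(m) == 0L) abort("no taxa: the count table is empty.")
  storage.mode(m) <- "double"
  if (anyNA(m) || any(m < 0) || any(m != round(m))) {
    bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)[1, , drop = TRUE]
    abort(sprintf(
      "counts must be non-negative integers; offending cell: taxon '%s', sample '%s'.",
      rownames(m)[bad[1]], colnames(m)[bad[2]]
    ))
  }
  dup <- duplicated(rownames(m))
  if (any(dup)) {
    abort(sprintf("duplicated taxon id(s): %s.",
                  paste(unique(rownames(m)[dup]), collapse = ", ")))
  }
  m
}

taxa_tibble <- function(m) {
  tibble::as_tibble(cbind(
    tibble::tibble(taxon = rownames(m)),
    tibble::as_tibble(m, .name_repair = "minimal")
  ))
}

# simple collecting logger used by the pipeline
new_logger <- function() {
  lines <- character()
  list(
    log = function(fmt, ...) {
      msg <- sprintf(fmt, ...)
      lines <<- c(lines, msg)
      inform(msg)
    },
    lines = function() lines
  )
}
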