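#' Gene-by-stage expression matrix
#'
#' Lightweight container for a developmental expression time course of one
#' species: a non-negative gene x sample matrix, ordered stage metadata with
#' a life-cycle phase tag per stage, the abundance layer the values live on,
#' and an optional stage-to-replicate-column map.
#'
#' @param values numeric matrix, genes in rows (rownames = gene IDs),
#'   samples in columns (colnames = sample labels).
#' @param species_id single character label for the species.
#' @param stage_info data.frame with columns `stage`, `ordinal`, `phase`
#'   (one of `"pre-larval"`, `"larval"`, `"post-larval"`, `"adult-tissue"`).
#'   Ordinals must be strictly increasing.
#' @param layer one of `"counts"`, `"tpm"`, `"normalized_counts"`,
#'   `"quantile_uniform"`, `"zscore"`.
#' @param replicate_map optional named list mapping each stage label to the
#'   character vector of column names holding its replicates. When `NULL`
#'   the columns are taken to be the stages themselves, in `stage_info`
#'   order.
#'
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, species_id, stage_info, layer,
                              replicate_map = NULL) {
  assert_that(is.matrix(values) && is.numeric(values),
              "values must be a numeric matrix")
  assert_that(!is.null(rownames(values)), "values must have gene rownames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) {
    stop("duplicate gene identifier: ", dup[[1]], call. = FALSE)
  }
  layer <- match.arg(layer, c("counts", "tpm", "normalized_counts",
                              "quantile_uniform", "zscore"))
  if (layer %in% c("counts", "tpm", "normalized_counts") &&
      any(values < 0, na.rm = TRUE)) {
    stop("negative values are not allowed on layer '", layer, "'",
         call. = FALSE)
  }
  stage_info <- as.data.frame(stage_info, stringsAsFactors = FALSE)
  assert_that(all(c("stage", "ordinal", "phase") %in% names(stage_info)),
              "stage_info needs columns stage, ordinal, phase")
  assert_that(!anyDuplicated(stage_info$stage),
              "stage labels must be unique")
  assert_that(all(diff(stage_info$ordinal) > 0),
              "stage ordinals must be strictly increasing")
  bad <- setdiff(stage_info$phase,
                 c("pre-larval", "larval", "post-larval", "adult-tissue"))
  assert_that(length(bad) == 0,
              paste0("unknown phase tag: ", paste(bad, collapse = ", ")))
  if (is.null(replicate_map)) {
    assert_that(all(stage_info$stage %in% colnames(values)),
                "every stage must have a matching column")
  } else {
    assert_that(setequal(names(replicate_map), stage_info$stage),
                "replicate_map names must equal the stage labels")
    cols <- unlist(replicate_map, use.names = FALSE)
    assert_that(all(cols %in% colnames(values)),
                "replicate_map refers to unknown columns")
    n0 <- vapply(replicate_map, length, integer(1))
    assert_that(all(n0 >= 1), "a stage has zero replicate columns")
  }
  structure(list(values = values, species_id = species_id,
                 stage_info = stage_info, layer = layer,
                 replicate_map = replicate_map),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s] %d genes x %d columns, layer=%s\n",
              x$species_id, nrow(x$values), ncol(x$values), x$layer))
  cat("  stages:", paste(x$stage_info$stage, collapse = ", "), "\n")
  if (!is.null(x$replicate_map)) {
    cat("  replicates per stage:",
        paste(vapply(x$replicate_map, length, integer(1)), collapse = ","),
        "\n")
  }
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Genes of an expression matrix
#' @param m an `ExpressionMatrix`.
#' @return character vector of gene identifiers.
#' @export
genes <- function(m) rownames(m$values)

#' Stage labels of an expression matrix
#' @param m an `ExpressionMatrix`.
#' @return character vector of ordered stage labels.
#' @export
stages <- function(m) m$stage_info$stage

#' Read a gene-by-sample expression table
#'
#' Reads a TSV (optionally gzip-compressed) whose header row holds sample
#' labels and whose first column holds gene identifiers, and wraps it into
#' an [expression_matrix()] according to `layout`.
#'
#' @param path path to the TSV file.
#' @param layout list with elements `species_id`, `layer`, and either
#'   `stage_info` (+ optional `replicate_map`) or nothing, in which case
#'   every column is treated as one stage with ordinal 1..n and phase
#'   `"larval"`.
#' @return an `ExpressionMatrix`.
#' @export
read_expression_table <- function(path, layout) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  assert_that(ncol(raw) >= 2, "table needs a gene column plus >=1 sample")
  ids <- as.character(raw[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate gene identifier: ", dup[[1]], call. = FALSE)
  }
  num <- raw[-1]
  for (j in seq_along(num)) {
    v <- num[[j]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("non-numeric value at row %d, column '%s'",
                     bad[[1]], names(num)[j]), call. = FALSE)
      }
      num[[j]] <- conv
    }
  }
  values <- as.matrix(num)
  rownames(values) <- ids
  stage_info <- layout$stage_info
  if (is.null(stage_info)) {
    stage_info <- data.frame(stage = colnames(values),
                             ordinal = seq_len(ncol(values)),
                             phase = "larval", stringsAsFactors = FALSE)
  }
  expression_matrix(values, species_id = layout$species_id,
                    stage_info = stage_info, layer = layout$layer,
                    replicate_map = layout$replicate_map)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_table()]: header = sample labels, first
#' column `gene`. Values are written at full precision.
#'
#' @param m an `ExpressionMatrix`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_expression_table <- function(m, path) {
  df <- data.frame(gene = genes(m), m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average replicate columns per stage
#'
#' Collapses the replicate columns of each stage to their arithmetic mean,
#' leaving one column per stage and clearing the replicate map.
#'
#' @param m an `ExpressionMatrix` with a `replicate_map`.
#' @return an `ExpressionMatrix` with one column per stage.
#' @export
average_replicates <- function(m) {
  assert_that(inherits(m, "ExpressionMatrix"), "not an ExpressionMatrix")
  if (is.null(m$replicate_map)) return(m)
  stg <- m$stage_info$stage
  out <- vapply(stg, function(s) {
    cols <- m$replicate_map[[s]]
    assert_that(length(cols) >= 1,
                paste0("stage '", s, "' has zero replicate columns"))
    rowMeans(m$values[, cols, drop = FALSE])
  }, numeric(nrow(m$values)))
  out <- matrix(out, nrow = nrow(m$values),
                dimnames = list(genes(m), stg))
  expression_matrix(out, m$species_id, m$stage_info, m$layer,
                    replicate_map = NULL)
}
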