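#' Orthology map across species
#'
#' Container for orthogroup membership: for every orthogroup, the genes it
#' holds in each species. A gene may belong to at most one orthogroup
#' within its species.
#'
#' @param memberships named list: orthogroup ID -> named list of species ->
#'   character vector of genes.
#' @return an object of class `OrthologyMap`.
#' @export
orthology_map <- function(memberships) {
  assert_that(is.list(memberships) && !is.null(names(memberships)),
              "memberships must be a named list of orthogroups")
  species <- unique(unlist(lapply(memberships, names)))
  gene2og <- lapply(species, function(sp) {
    gs <- lapply(memberships, function(og) og[[sp]] %||% character(0))
    v <- rep(names(memberships), vapply(gs, length, integer(1)))
    names(v) <- unlist(gs, use.names = FALSE)
    dup <- names(v)[duplicated(names(v))]
    if (length(dup)) {
      stop("gene '", dup[[1]], "' of species '", sp,
           "' maps to more than one orthogroup", call. = FALSE)
    }
    v
  })
  names(gene2og) <- species
  structure(list(memberships = memberships, species = species,
                 gene2og = gene2og),
            class = "OrthologyMap")
}

#' @export
print.OrthologyMap <- function(x, ...) {
  cat(sprintf("OrthologyMap: %d orthogroups, species: %s\n",
              length(x$memberships), paste(x$species, collapse = ", ")))
  invisible(x)
}

#' One-to-one orthologue pairs between two species
#'
#' Restricts the map to orthogroups holding exactly one gene in each of
#' the two species.
#'
#' @param map an `OrthologyMap`.
#' @param species_a,species_b species identifiers present in the map.
#' @return data.frame with columns `orthogroup`, `gene_a`, `gene_b`.
#' @export
one_to_one <- function(map, species_a, species_b) {
  assert_that(inherits(map, "OrthologyMap"), "not an OrthologyMap")
  assert_that(all(c(species_a, species_b) %in% map$species),
              "unknown species in one_to_one()")
  keep <- vapply(map$memberships, function(og) {
    length(og[[species_a]] %||% character(0)) == 1 &&
      length(og[[species_b]] %||% character(0)) == 1
  }, logical(1))
  ogs <- names(map$memberships)[keep]
  data.frame(
    orthogroup = ogs,
    gene_a = vapply(map$memberships[keep], function(og) og[[species_a]],
                    character(1)),
    gene_b = vapply(map$memberships[keep], function(og) og[[species_b]],
                    character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Read an Orthogroups.tsv-style table
#'
#' Parses the OrthoFinder dialect: first column the orthogroup ID, one
#' column per species holding a comma-separated gene list (empty when the
#' species lacks the orthogroup).
#'
#' @param path path to the TSV.
#' @return an `OrthologyMap`.
#' @export
read_orthogroups <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  assert_that(ncol(raw) >= 2, "orthogroup table needs >= 2 columns")
  species <- colnames(raw)[-1]
  mem <- lapply(seq_len(nrow(raw)), function(i) {
    row <- lapply(species, function(sp) {
      gs <- strsplit(raw[i, sp], ",\\s*")[[1]]
      gs[nzchar(gs)]
    })
    names(row) <- species
    row[vapply(row, length, integer(1)) > 0]
  })
  names(mem) <- raw[[1]]
  orthology_map(mem)
}

#' Write an OrthologyMap as Orthogroups.tsv
#'
#' @param map an `OrthologyMap`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_orthogroups <- function(map, path) {
  df <- data.frame(Orthogroup = names(map$memberships),
                   stringsAsFactors = FALSE)
  for (sp in map$species) {
    df[[sp]] <- vapply(map$memberships, function(og) {
      paste(og[[sp]] %||% character(0), collapse = ", ")
    }, character(1))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
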