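#' Parameter-gene coupling map
#'
#' Records which genes are assigned to which kinetic parameters; the two
#' gene-regularization terms act only on coupled parameters. A parameter may
#' carry zero, one or several genes (a cascade of molecular processes lumped
#' into one rate law can be informed by several transcripts).
#'
#' @param couples data frame with columns `parameter` and `gene`; duplicated
#'   pairs are rejected.
#' @return a tibble of class `gene_coupling_map`.
#' @export
gene_coupling_map <- function(couples) {
  couples <- tibble::as_tibble(couples)
  stopifnot(all(c("parameter", "gene") %in% names(couples)))
  couples$parameter <- as.character(couples$parameter)
  couples$gene <- as.character(couples$gene)
  if (anyDuplicated(couples[c("parameter", "gene")])) {
    stop("duplicate parameter-gene couples")
  }
  class(couples) <- c("gene_coupling_map", class(couples))
  couples
}

#' @rdname gene_coupling_map
#' @param map a coupling map.
#' @param model optional [metabolic_model()]: every coupled parameter must be
#'   a model parameter.
#' @param genes optional character vector of available transcript observables:
#'   every coupled gene must be present.
#' @export
validate_coupling <- function(map, model = NULL, genes = NULL) {
  map <- gene_coupling_map(map)
  if (!is.null(model)) {
    bad <- setdiff(unique(map$parameter), model$parameters$name)
    if (length(bad)) stop("coupling references unknown parameter(s): ", toString(bad))
  }
  if (!is.null(genes)) {
    bad <- setdiff(unique(map$gene), genes)
    if (length(bad)) stop("coupling references unknown gene(s): ", toString(bad))
  }
  invisible(map)
}

#' Read / write a coupling map as delimited text
#'
#' @param path CSV file with columns `parameter, gene`.
#' @return a `gene_coupling_map`.
#' @export
read_coupling_csv <- function(path) {
  gene_coupling_map(readr::read_csv(path, show_col_types = FALSE,
                                    col_types = "cc"))
}

#' @rdname read_coupling_csv
#' @param map a `gene_coupling_map`.
#' @export
write_coupling_csv <- function(map, path) {
  readr::write_csv(tibble::as_tibble(map)[c("parameter", "gene")], path)
  invisible(path)
}

# split into list parameter -> character vector of genes
.couples_by_parameter <- function(map) {
  split(map$gene, map$parameter)
}
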