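#' Write / read a genetic map CSV
#'
#' Columns `marker`, `chromosome`, `position_cM`.
#'
#' @param map a `genetic_map`.
#' @param path CSV path.
#' @return `write_map`: the path, invisibly. `read_map`: a `genetic_map`.
#' @export
write_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(chromosome = "character"))
  need <- c("marker", "chromosome", "position_cM")
  if (!all(need %in% names(d))) {
    stop("map file must have columns ", paste(need, collapse = ", "))
  }
  genetic_map(d$marker, d$chromosome, d$position_cM)
}

#' Write / read a genotype CSV
#'
#' The rotated orientation (default) has markers as rows: `marker`,
#' `chromosome`, `position_cM`, then one column per line with calls in
#' {A, B, NA}. `transposed = TRUE` reads/writes lines as rows instead
#' (first column `line`, then one column per marker).
#'
#' @param genotypes a `genotype_matrix`.
#' @param path CSV path.
#' @param transposed use the lines-as-rows orientation.
#' @return `write_genotypes`: the path, invisibly.
#' @export
write_genotypes <- function(genotypes, path, transposed = FALSE) {
  map <- attr(genotypes, "map")
  if (transposed) {
    d <- data.frame(line = rownames(genotypes),
                    unclass(genotypes)[, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    d <- data.frame(map[, c("marker", "chromosome", "position_cM")],
                    t(unclass(genotypes)), check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read map + genotypes together, cross-validated
#'
#' @param map_path map CSV (see [read_map()]).
#' @param genotype_path genotype CSV (see [write_genotypes()]).
#' @param transposed genotype file orientation flag.
#' @return list(map = `genetic_map`, genotypes = `genotype_matrix`).
#' @export
read_genotype_map <- function(map_path, genotype_path, transposed = FALSE) {
  map <- read_map(map_path)
  d <- utils::read.csv(genotype_path, stringsAsFactors = FALSE,
                       check.names = FALSE)
  if (transposed) {
    if (names(d)[1] != "line") stop("transposed genotype file needs a 'line' first column")
    calls <- as.matrix(d[, -1, drop = FALSE])
    rownames(calls) <- d$line
  } else {
    meta <- intersect(c("marker", "chromosome", "position_cM"), names(d))
    if (!"marker" %in% meta) stop("genotype file needs a 'marker' column")
    calls <- t(as.matrix(d[, setdiff(names(d), meta), drop = FALSE]))
    colnames(calls) <- d$marker
  }
  storage.mode(calls) <- "character"
  calls[calls == ""] <- NA_character_
  extra <- setdiff(colnames(calls), map$marker)
  if (length(extra)) {
    stop("genotype marker(s) absent from map: ", paste(extra, collapse = ", "))
  }
  missing <- setdiff(map$marker, colnames(calls))
  if (length(missing)) {
    stop("map marker(s) absent from genotype file: ",
         paste(missing, collapse = ", "))
  }
  list(map = map, genotypes = genotype_matrix(calls, map))
}

#' Write / read a long-format trait table CSV
#'
#' Columns `line`, `experiment`, `block`, `trait`, `value`; one row per
#' replicated observation. Duplicate (line, experiment, block, trait) keys
#' and non-numeric values are rejected on read.
#'
#' @param traits a `trait_table`.
#' @param path CSV path.
#' @return `write_traits`: the path invisibly; `read_trait_table`: a
#'   `trait_table`.
#' @export
write_traits <- function(traits, path) {
  utils::write.csv(as.data.frame(traits), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traits
#' @export
read_trait_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line", "experiment", "block", "trait", "value")
  if (!all(need %in% names(d))) {
    stop("trait file must have columns ", paste(need, collapse = ", "))
  }
  if (!is.numeric(d$value)) stop("non-numeric trait values")
  key <- paste(d$line, d$experiment, d$block, d$trait, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicated observation key(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "))
  }
  d <- d[, need]
  class(d) <- c("trait_table", "data.frame")
  d
}
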