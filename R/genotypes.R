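# Population-structured microsatellite genotypes: integer repeat counts at
# unlinked loci, two gene copies per individual, NA = missing.

#' Construct a genotype dataset
#'
#' @param geno integer matrix of repeat counts, one row per gene copy (two
#'   consecutive rows per individual), one column per locus; `NA` marks
#'   missing alleles.
#' @param pop character/factor of population labels, one per gene row.
#' @param groups named character vector mapping population labels to
#'   regional groups (AFR/ENA/CAS/EAS).
#' @param loci optional locus labels.
#' @return a `genotype_dataset`.
#' @export
genotype_dataset <- function(geno, pop, groups, loci = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(nrow(geno) == length(pop), nrow(geno) %% 2 == 0)
  if (any(geno[!is.na(geno)] < 1))
    stop("repeat counts must be positive integers")
  pop <- as.character(pop)
  if (!all(unique(pop) %in% names(groups)))
    stop("every population needs a group assignment")
  if (is.null(loci))
    loci <- paste0("L", seq_len(ncol(geno)))
  if (ncol(geno) > 0) colnames(geno) <- loci
  # individual ids: consecutive gene-row pairs, numbered within population
  odd <- seq(1, nrow(geno), by = 2)
  if (!all(pop[odd] == pop[odd + 1]))
    stop("the two gene rows of an individual must share a population")
  within <- ave(seq_along(odd), pop[odd], FUN = seq_along)
  ind <- rep(paste0(pop[odd], "_i", within), each = 2)
  structure(list(geno = geno, pop = pop, indiv = ind,
                 groups = groups[unique(pop)]),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("<genotype_dataset> ", length(unique(x$pop)), " populations, ",
      nrow(x$geno) / 2, " diploids, ", ncol(x$geno), " loci\n", sep = "")
  miss <- mean(is.na(x$geno))
  cat("  groups: ", paste(sort(unique(x$groups)), collapse = " "),
      ";  missing: ", sprintf("%.2f%%", 100 * miss), "\n", sep = "")
  invisible(x)
}

#' Number of populations / loci in a dataset
#' @param dataset a `genotype_dataset`.
#' @export
n_populations <- function(dataset) length(unique(dataset$pop))

#' @rdname n_populations
#' @export
n_loci <- function(dataset) ncol(dataset$geno)

#' Subset a dataset to a set of loci
#' @param dataset a `genotype_dataset`.
#' @param loci column indices or names.
#' @return a `genotype_dataset`.
#' @export
subset_loci <- function(dataset, loci) {
  out <- dataset
  out$geno <- dataset$geno[, loci, drop = FALSE]
  out
}

#' Write / read genotypes as TSV
#'
#' Long format, one row per individual and locus: columns `pop`, `indiv`,
#' `locus`, `allele1`, `allele2`; `-9` marks missing alleles.  A `group`
#' column preserves the regional group map.
#'
#' @param dataset a `genotype_dataset`.
#' @param path file path.
#' @export
write_genotypes <- function(dataset, path) {
  g <- dataset$geno
  i1 <- seq(1, nrow(g), by = 2)
  df <- do.call(rbind, lapply(seq_len(ncol(g)), function(l)
    data.frame(pop = dataset$pop[i1], indiv = dataset$indiv[i1],
               group = unname(dataset$groups[dataset$pop[i1]]),
               locus = colnames(g)[l],
               allele1 = ifelse(is.na(g[i1, l]), -9L, g[i1, l]),
               allele2 = ifelse(is.na(g[i1 + 1, l]), -9L, g[i1 + 1, l]),
               stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  loci <- unique(df$locus)
  inds <- unique(df[c("pop", "indiv", "group")])
  geno <- matrix(NA_integer_, 2L * nrow(inds), length(loci),
                 dimnames = list(NULL, loci))
  key <- match(paste(df$pop, df$indiv), paste(inds$pop, inds$indiv))
  lix <- match(df$locus, loci)
  a1 <- ifelse(df$allele1 == -9L, NA_integer_, df$allele1)
  a2 <- ifelse(df$allele2 == -9L, NA_integer_, df$allele2)
  geno[cbind(2L * key - 1L, lix)] <- a1
  geno[cbind(2L * key, lix)] <- a2
  genotype_dataset(geno, pop = rep(inds$pop, each = 2),
                   groups = setNames(inds$group, inds$pop)[
                     !duplicated(inds$pop)],
                   loci = loci)
}

#' Write genotypes in STRUCTURE format
#'
#' Two rows per individual (one per gene copy): individual label, a numeric
#' population index, then one allele per locus (`-9` = missing).
#'
#' @param dataset a `genotype_dataset`.
#' @param path file path.
#' @export
write_structure <- function(dataset, path) {
  g <- dataset$geno
  g[is.na(g)] <- -9L
  popix <- as.integer(factor(dataset$pop, levels = unique(dataset$pop)))
  out <- cbind(dataset$indiv, popix, g)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("indiv", "pop", colnames(g)), collapse = "\t"), con)
  apply(out, 1, function(rw) writeLines(paste(rw, collapse = "\t"), con))
  invisible(path)
}

#' Inject missing data completely at random
#'
#' @param dataset a `genotype_dataset`.
#' @param rate per-allele missingness probability (at most 0.05 to match
#'   the filtered-panel convention).
#' @return a `genotype_dataset` with NAs injected.
#' @export
inject_missing <- function(dataset, rate) {
  stopifnot(rate >= 0, rate <= 0.05)
  out <- dataset
  drop <- runif(length(out$geno)) < rate
  out$geno[drop] <- NA_integer_
  out
}
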