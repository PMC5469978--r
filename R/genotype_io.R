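#' Construct a genotype table
#'
#' A genotype table holds multilocus codominant genotypes: one row per
#' individual, with a population label, an optional sampling year, and two
#' allele columns per locus (`<locus>.1`, `<locus>.2`). Allele labels are
#' stored as character strings; a locus entry is missing iff either allele
#' is `NA`, in which case both are normalised to `NA`.
#'
#' @param df data.frame with columns `individual`, `population`, optionally
#'   `year`, then two columns per locus named `<locus>.1`, `<locus>.2`.
#' @return A validated `genotype_table` (a data.frame subclass with a
#'   `loci` attribute).
#' @export
genotype_table <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("individual", "population") %in% names(df)))
    stop("genotype table needs 'individual' and 'population' columns")
  if (!"year" %in% names(df)) df$year <- NA_integer_
  meta <- c("individual", "population", "year")
  allele_cols <- setdiff(names(df), meta)
  if (length(allele_cols) == 0L || length(allele_cols) %% 2L != 0L)
    stop("expected an even, positive number of allele columns (two per locus)")
  loci <- unique(sub("\\.[12]$", "", allele_cols))
  expected <- as.vector(rbind(paste0(loci, ".1"), paste0(loci, ".2")))
  if (!setequal(allele_cols, expected))
    stop("allele columns must come in pairs '<locus>.1', '<locus>.2'")
  df <- df[, c(meta, expected)]
  df$individual <- as.character(df$individual)
  df$population <- as.character(df$population)
  df$year <- suppressWarnings(as.integer(df$year))
  for (lc in loci) {
    a <- as.character(df[[paste0(lc, ".1")]])
    b <- as.character(df[[paste0(lc, ".2")]])
    miss <- is.na(a) | is.na(b)
    a[miss] <- NA_character_
    b[miss] <- NA_character_
    df[[paste0(lc, ".1")]] <- a
    df[[paste0(lc, ".2")]] <- b
  }
  if (nrow(df) == 0L) stop("genotype table has no individuals")
  attr(df, "loci") <- loci
  class(df) <- c("genotype_table", "data.frame")
  df
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals, %d populations, %d loci\n",
              nrow(x), length(unique(x$population)), length(attr(x, "loci"))))
  invisible(x)
}

#' Loci of a genotype table
#' @param table a `genotype_table`
#' @return character vector of locus names
#' @export
loci_names <- function(table) attr(table, "loci")

#' Read genotypes from CSV or Genepop
#'
#' The CSV dialect has columns `individual`, `population`, optional `year`,
#' then two columns per locus. The Genepop dialect follows the classic
#' layout (title line, locus names, `POP` separators, `id , a1a2 ...`);
#' 2- or 3-digit allele codes are auto-detected and `00`/`000` (or
#' `0000`/`000000` for the diploid call) is the missing code.
#'
#' @param path file path
#' @param dialect `"csv"` or `"genepop"`
#' @return a `genotype_table`
#' @export
read_genotypes <- function(path, dialect = c("csv", "genepop")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
    for (cn in setdiff(names(df), c("individual", "population", "year")))
      df[[cn]][df[[cn]] == ""] <- NA_character_
    genotype_table(df)
  } else {
    read_genepop(path)
  }
}

read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("malformed Genepop file: too few lines")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("malformed Genepop file: no POP line")
  # locus names: one per line, or comma-separated on one line
  locus_lines <- lines[2:(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  rows <- list()
  pop_idx <- 0L
  for (i in seq(first_pop, length(lines))) {
    ln <- lines[i]
    if (toupper(trimws(ln)) == "POP") { pop_idx <- pop_idx + 1L; next }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2L)
      stop(sprintf("parse error at line %d: expected 'id , genotypes'", i))
    id <- trimws(parts[1])
    calls <- strsplit(trimws(paste(parts[-1], collapse = " ")), "[[:space:]]+")[[1]]
    if (length(calls) != length(loci))
      stop(sprintf("parse error at line %d: %d genotype fields for %d loci",
                   i, length(calls), length(loci)))
    width <- nchar(calls[1]) / 2L
    if (!width %in% c(2L, 3L) || any(nchar(calls) != 2L * width))
      stop(sprintf("parse error at line %d: inconsistent allele code width", i))
    a1 <- substr(calls, 1L, width)
    a2 <- substr(calls, width + 1L, 2L * width)
    miss <- strrep("0", width)
    a1[a1 == miss] <- NA_character_
    a2[a2 == miss] <- NA_character_
    rows[[length(rows) + 1L]] <- c(list(individual = id,
                                        population = paste0("pop", pop_idx)),
                                   stats::setNames(as.list(a1), paste0(loci, ".1")),
                                   stats::setNames(as.list(a2), paste0(loci, ".2")))
  }
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE,
                                                              check.names = FALSE)))
  genotype_table(df)
}

#' Write genotypes to CSV or Genepop
#' @param table a `genotype_table`
#' @param path output file
#' @param dialect `"csv"` or `"genepop"`
#' @export
write_genotypes <- function(table, path, dialect = c("csv", "genepop")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
    return(invisible(path))
  }
  loci <- loci_names(table)
  all_alleles <- unlist(lapply(loci, function(lc)
    c(table[[paste0(lc, ".1")]], table[[paste0(lc, ".2")]])))
  width <- if (all(is.na(all_alleles)) ||
               max(nchar(all_alleles), na.rm = TRUE) <= 2L) 2L else 3L
  fmt <- function(a) ifelse(is.na(a), strrep("0", width),
                            formatC(a, width = width, flag = "0"))
  out <- c("genotype export", loci)
  for (pop in unique(table$population)) {
    out <- c(out, "POP")
    sub <- table[table$population == pop, , drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      calls <- vapply(loci, function(lc)
        paste0(fmt(sub[[paste0(lc, ".1")]][r]), fmt(sub[[paste0(lc, ".2")]][r])),
        character(1))
      out <- c(out, paste0(sub$individual[r], " , ", paste(calls, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read / write a site table
#'
#' Sites carry a population label, short abbreviation, projected planar
#' coordinates in metres, species label, and an `included` flag (excluded
#' sites are kept but flagged rather than deleted).
#'
#' @param path CSV path with columns population, abbrev, x, y, species, included
#' @return data.frame of class `site_table`
#' @export
read_sites <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  site_table(df)
}

#' @rdname read_sites
#' @param df data.frame with the site columns
#' @export
site_table <- function(df) {
  need <- c("population", "abbrev", "x", "y")
  if (!all(need %in% names(df)))
    stop("site table needs columns: ", paste(need, collapse = ", "))
  if (!"species" %in% names(df)) df$species <- NA_character_
  if (!"included" %in% names(df)) df$included <- TRUE
  if (anyDuplicated(df$abbrev)) stop("site abbreviations must be unique")
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("site coordinates must be finite")
  class(df) <- c("site_table", "data.frame")
  df
}

#' @rdname read_sites
#' @param sites a `site_table`
#' @export
write_sites <- function(sites, path) {
  utils::write.csv(as.data.frame(sites), path, row.names = FALSE)
  invisible(path)
}

# G statistic (likelihood-ratio) for an allele-count contingency table
g_statistic <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (length(tab) == 0L || any(dim(tab) < 2L)) return(0)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  obs <- tab[tab > 0]
  2 * sum(obs * log(obs / expected[tab > 0]))
}

#' Test allele-frequency homogeneity between two sampling years
#'
#' Before pooling samples collected in different years from the same
#' population, checks per-locus allele-frequency homogeneity with a
#' permutation G-test (individual labels permuted between years), and
#' combines the per-locus p-values with Fisher's method. Pooling is
#' recommended when the combined p-value is at least 0.05.
#'
#' @param table a `genotype_table` with a `year` column
#' @param population population label
#' @param year_a,year_b the two years to compare
#' @param n_perm number of label permutations (>= 99)
#' @param seed integer seed for the permutations
#' @return list with `per_locus` (named p-value vector), `combined_p`,
#'   `fisher_chisq`, `df`, and `pool_recommended`
#' @export
temporal_pooling_test <- function(table, population, year_a, year_b,
                                  n_perm = 999, seed = 1L) {
  stopifnot(n_perm >= 99)
  sub <- table[table$population == population, , drop = FALSE]
  for (yr in c(year_a, year_b))
    if (!any(sub$year == yr, na.rm = TRUE))
      stop(sprintf("population '%s' has no samples for year %s", population, yr))
  sub <- sub[sub$year %in% c(year_a, year_b), , drop = FALSE]
  grp <- factor(sub$year, levels = c(year_a, year_b))
  loci <- loci_names(table)
  set.seed(seed)
  perms <- replicate(n_perm, sample(seq_len(nrow(sub))), simplify = FALSE)

  locus_p <- vapply(loci, function(lc) {
    a1 <- sub[[paste0(lc, ".1")]]
    a2 <- sub[[paste0(lc, ".2")]]
    keep <- !is.na(a1)
    if (sum(keep) < 2L) return(NA_real_)
    count_tab <- function(g) {
      alle <- c(a1[keep], a2[keep])
      gg <- c(g[keep], g[keep])
      as.matrix(table(factor(alle), gg))
    }
    obs <- g_statistic(count_tab(grp))
    perm_g <- vapply(perms, function(p) g_statistic(count_tab(grp[p])), numeric(1))
    (1 + sum(perm_g >= obs)) / (n_perm + 1)
  }, numeric(1))

  ok <- !is.na(locus_p)
  chisq <- -2 * sum(log(locus_p[ok]))
  df <- 2L * sum(ok)
  combined <- stats::pchisq(chisq, df = df, lower.tail = FALSE)
  list(per_locus = locus_p, combined_p = combined,
       fisher_chisq = chisq, df = df,
       pool_recommended = combined >= 0.05)
}

#' Fisher's method for combining independent p-values
#' @param p vector of p-values in (0, 1]
#' @return list with `chisq`, `df`, `p`
#' @export
fisher_combine <- function(p) {
  p <- p[!is.na(p)]
  chisq <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(chisq = chisq, df = df, p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Pool temporal samples within a population
#'
#' Merges the given years of one population into a single stratum (year set
#' to `NA`); all other rows pass through unchanged. Callers are expected to
#' have consulted [temporal_pooling_test()]; `force` records an override.
#'
#' @param table a `genotype_table`
#' @param population population label
#' @param years integer vector of years to merge
#' @param force logical; pool even if not recommended (logged via message)
#' @return a `genotype_table`
#' @export
pool_samples <- function(table, population, years, force = FALSE) {
  sel <- table$population == population & table$year %in% years
  if (!any(sel)) stop("no rows match the requested population/years")
  if (force) message("pooling forced for population ", population)
  table$year[sel] <- NA_integer_
  genotype_table(as.data.frame(table))
}
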