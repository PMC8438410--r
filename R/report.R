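#' Run the full germplasm analysis and write a report bundle
#'
#' Orchestrates the whole pipeline on one genotype matrix: the per-locus
#' diversity panel, the UPGMA dendrogram of all accessions, identity-card
#' construction over a greedy PIC-ordered discriminating marker set (or a
#' caller-imposed marker order), stepwise core-collection extraction and the
#' comparison against random pseudo-cores. All output files are plain text
#' (TSV / Newick / JSON) and carry the seed and package version in a comment
#' header, so a bundle is reproducible from (input, parameters, seed).
#'
#' @param x an [ssr_matrix()], or a file path readable by [read_genotypes()]
#' @param out_dir output directory, created if needed
#' @param target_fraction,size core size specification, exactly one of the
#'   two (see [stepwise_core()])
#' @param seed integer seed governing core selection, pseudo-cores and the
#'   permutation test
#' @param reps number of random pseudo-cores (default 3)
#' @param markers optional fixed identity marker order; default: greedy
#'   selection by [select_discriminating_markers()]
#' @param n_perm permutations for [compare_collections()]
#' @return invisibly, a list with elements `stats`, `tree`, `scheme`,
#'   `identities`, `core` and `comparison`; files `locus_stats.tsv`,
#'   `tree.nwk`, `identities.tsv`, `core_members.txt`, `comparison.tsv` and
#'   `selection_log.json` are written under `out_dir`
#' @export
run_full_analysis <- function(x, out_dir, target_fraction = NULL, size = NULL,
                              seed = 1L, reps = 3L, markers = NULL,
                              n_perm = 999L) {
  if (is.character(x)) x <- read_genotypes(x)
  stopifnot(inherits(x, "ssr_matrix"))
  if (is.null(size) && is.null(target_fraction)) target_fraction <- 0.2
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# ssrcore %s | seed %s",
                 as.character(utils::packageVersion("ssrcore")), seed)
  put <- function(lines, file) writeLines(c(hdr, lines),
                                          file.path(out_dir, file))
  tsv <- function(df) c(paste(names(df), collapse = "\t"),
                        apply(df, 1L, function(r) paste(trimws(r), collapse = "\t")))

  stats_tab <- locus_stats_table(x)
  num <- vapply(stats_tab, is.numeric, TRUE)
  stats_out <- stats_tab
  stats_out[num] <- lapply(stats_out[num], function(v) sprintf("%.4f", v))
  put(tsv(stats_out), "locus_stats.tsv")

  tree <- upgma(allele_sharing_dist(x))
  writeLines(to_newick(tree), file.path(out_dir, "tree.nwk"))

  if (is.null(markers)) {
    scheme <- select_discriminating_markers(x)
    markers <- scheme$markers
  } else {
    scheme <- list(markers = markers, complete = NA, collisions = list())
  }
  ident <- build_identities(x, markers)
  uniq <- verify_uniqueness(ident)
  put(c(paste0("# markers: ", paste(markers, collapse = ",")),
        paste0("# all_distinct: ", uniq$unique),
        "accession\tidentity",
        paste(names(ident), ident, sep = "\t")),
      "identities.tsv")

  core <- stepwise_core(x, target_fraction = target_fraction, size = size,
                        seed = seed)
  put(core$selected, "core_members.txt")
  rnd <- random_cores(x, size = length(core$selected), reps = reps,
                      seed = seed + 1L)
  names(rnd) <- paste0("random", seq_along(rnd))
  cmp <- compare_collections(x, c(list(core = core$selected), rnd),
                             n_perm = n_perm, seed = seed + 2L)
  mean_tab <- data.frame(collection = rownames(cmp$means),
                         round(cmp$means, 4))
  put(c(tsv(mean_tab), "", tsv(cmp$tests)), "comparison.tsv")

  jsonlite::write_json(
    list(seed = seed, target = core$target, fraction = core$fraction,
         rounds = core$rounds, selected = core$selected,
         retention = as.list(core$retention)),
    file.path(out_dir, "selection_log.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(stats = stats_tab, tree = tree, scheme = scheme,
                 identities = ident, core = core, comparison = cmp))
}
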