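# Readers and writers for the study's tabular interchange formats:
# Bismark-coverage-style per-individual methylation TSVs, a wide count
# matrix, behavioral CSVs, pedigree TSV, and the ground-truth JSON.

#' Write methylation counts as Bismark-coverage-style files
#'
#' One headerless TSV per individual with columns chrom, start (1-based),
#' end, percent methylation, count methylated, count unmethylated.
#'
#' @param counts a [meth_counts()] object.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_bismark_cov <- function(counts, dir) {
  .assert(inherits(counts, "meth_counts"), "need a meth_counts object")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(counts$individuals, function(id) {
    me <- counts$meth[, id]
    to <- counts$total[, id]
    df <- data.frame(chrom = counts$sites$chrom,
                     start = counts$sites$pos + 1L,
                     end = counts$sites$pos + 1L,
                     percent = ifelse(to > 0, 100 * me / to, 0),
                     count_methylated = me,
                     count_unmethylated = to - me)
    p <- file.path(dir, paste0(id, ".cov"))
    data.table::fwrite(df, p, sep = "\t", col.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Read Bismark-coverage-style files into a meth_counts object
#'
#' Input columns: chrom, start (1-based inclusive), end, percent, count
#' methylated, count unmethylated.  Positions are converted to the 0-based
#' internal convention.  Sites are the union across files; cells absent
#' from a file get total = 0 (removed later by the coverage filter).
#'
#' @param files vector of file paths.
#' @param ids individual ids (defaults to file base names).
#' @return a [meth_counts()] object.
#' @export
read_bismark_cov <- function(files, ids = NULL) {
  .assert(length(files) >= 1, "no files given")
  ids <- ids %||% sub("\\.[^.]*$", "", basename(files))
  tabs <- lapply(files, function(f) {
    dt <- data.table::fread(f, header = FALSE,
                            col.names = c("chrom", "start", "end", "percent",
                                          "count_methylated",
                                          "count_unmethylated"))
    dt$pos <- dt$start - 1L
    dt
  })
  all_sites <- unique(data.table::rbindlist(
    lapply(tabs, function(d) d[, c("chrom", "pos")])))
  data.table::setorder(all_sites, chrom, pos)
  site_id <- paste0(all_sites$chrom, ":", all_sites$pos)
  S <- nrow(all_sites)
  meth <- total <- matrix(0L, S, length(ids),
                          dimnames = list(site_id, ids))
  for (j in seq_along(tabs)) {
    key <- paste0(tabs[[j]]$chrom, ":", tabs[[j]]$pos)
    i <- match(key, site_id)
    meth[i, j] <- as.integer(tabs[[j]]$count_methylated)
    total[i, j] <- as.integer(tabs[[j]]$count_methylated +
                                tabs[[j]]$count_unmethylated)
  }
  meth_counts(meth, total,
              data.frame(chrom = all_sites$chrom, pos = all_sites$pos,
                         site_id = site_id, stringsAsFactors = FALSE))
}

#' Write a wide methylation count matrix
#'
#' One TSV with chrom, pos (0-based), then `meth_<id>` and `total_<id>`
#' column pairs.
#'
#' @param counts a [meth_counts()] object.
#' @param path output TSV path.
#' @export
write_meth_matrix <- function(counts, path) {
  .assert(inherits(counts, "meth_counts"), "need a meth_counts object")
  df <- data.frame(chrom = counts$sites$chrom, pos = counts$sites$pos)
  for (id in counts$individuals) {
    df[[paste0("meth_", id)]] <- counts$meth[, id]
    df[[paste0("total_", id)]] <- counts$total[, id]
  }
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a wide methylation count matrix
#'
#' @param path TSV written by [write_meth_matrix()].
#' @return a [meth_counts()] object.
#' @export
read_meth_matrix <- function(path) {
  dt <- as.data.frame(data.table::fread(path))
  ids <- sub("^meth_", "", grep("^meth_", names(dt), value = TRUE))
  meth <- as.matrix(dt[, paste0("meth_", ids), drop = FALSE])
  total <- as.matrix(dt[, paste0("total_", ids), drop = FALSE])
  colnames(meth) <- colnames(total) <- ids
  meth_counts(meth, total,
              data.frame(chrom = dt$chrom, pos = dt$pos,
                         site_id = paste0(dt$chrom, ":", dt$pos),
                         stringsAsFactors = FALSE))
}

#' Write a complete synthetic study to disk
#'
#' Emits the study's interchange files: covariates CSV, FAS records CSV,
#' sessions CSV (semicolon-delimited present ids), fGCM CSV, pedigree TSV
#' (id, mother, sex), Bismark-coverage-style methylation TSVs plus the wide
#' matrix, network edge lists and per-individual metrics, and a
#' ground-truth JSON with the planted parameters.
#'
#' @param study a [simulate_study()] object.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  .assert(inherits(study, "soc_study"), "need a soc_study")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(study$individuals, file.path(dir, "covariates.csv"))
  data.table::fwrite(study$fas, file.path(dir, "fas_records.csv"))
  sess <- stats::aggregate(id ~ session_id + date + ampm, data = study$sessions,
                           FUN = function(v) paste(v, collapse = ";"))
  names(sess)[names(sess) == "id"] <- "present_ids"
  data.table::fwrite(sess[order(sess$session_id), ],
                     file.path(dir, "sessions.csv"))
  data.table::fwrite(study$fgcm, file.path(dir, "fgcm.csv"))
  ped <- data.frame(id = study$pedigree$individual_id,
                    mother = study$pedigree$mother_id,
                    sex = study$pedigree$sex)
  data.table::fwrite(ped, file.path(dir, "pedigree.tsv"), sep = "\t")
  data.table::fwrite(study$network_metrics,
                     file.path(dir, "network_metrics.csv"))
  write_bismark_cov(study$meth, file.path(dir, "bismark"))
  write_meth_matrix(study$meth, file.path(dir, "meth_matrix.tsv"))
  gt <- study$ground_truth
  jsonlite::write_json(
    list(effects = unclass(gt$effects),
         b_id = as.list(gt$b_id),
         b_mom = as.list(gt$b_mom),
         true_site_ids = gt$true_site_ids,
         site = gt$site[, c("site_id", "beta_site", "is_true")],
         meth_sample_ids = study$meth_sample_ids,
         seed = study$config$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write an association network as a TSV edge list
#'
#' Three columns: `node_a`, `node_b`, `weight`.
#'
#' @param network a [build_network()] object.
#' @param path output TSV path.
#' @export
write_network_edges <- function(network, path) {
  .assert(inherits(network, "assoc_network"), "need an assoc_network")
  e <- network$edges
  data.table::fwrite(data.frame(node_a = e$a, node_b = e$b,
                                weight = e$weight),
                     path, sep = "\t")
  invisible(path)
}

#' Parse a sessions CSV with semicolon-delimited present ids
#'
#' @param path CSV with columns `session_id`, `date`, `ampm`, `present_ids`.
#' @return long-format data frame (`session_id`, `date`, `ampm`, `id`).
#' @export
read_sessions_csv <- function(path) {
  w <- as.data.frame(data.table::fread(path))
  ids <- strsplit(as.character(w$present_ids), ";", fixed = TRUE)
  n <- lengths(ids)
  data.frame(session_id = rep(w$session_id, n),
             date = as.Date(rep(as.character(w$date), n)),
             ampm = rep(w$ampm, n),
             id = unlist(ids), stringsAsFactors = FALSE)
}
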