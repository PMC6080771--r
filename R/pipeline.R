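#' Assemble and validate a pipeline configuration
#'
#' Either pass a JSON file path (all keys below) or named arguments. CLI
#' flags of the bundled `medipcpg` script override config-file keys.
#'
#' @param config a named list or a path to a JSON config file.
#' @param ... individual keys overriding `config`: `reads_a`, `reads_b`
#'   (BED paths; `reads_b` optional), `mre_a`, `mre_b` (optional BED),
#'   `reference` (FASTA) or `cpg_table` (TSV), `blacklist` (BED, optional),
#'   `link_dist` (default: maximum observed read length), `min_overlap`
#'   (1 or 2), `model` ("multinomial"/"bernoulli"), `tol`, `max_iter`,
#'   `test_method`, `cutoffs`, `seed`, `out_dir`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list(), ...) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  override <- list(...)
  config[names(override)] <- override
  defaults <- list(reads_b = NULL, mre_a = NULL, mre_b = NULL,
                   reference = NULL, cpg_table = NULL, blacklist = NULL,
                   link_dist = NULL, min_overlap = 1L,
                   model = "multinomial", tol = 1e-6, max_iter = 1e4,
                   test_method = "fisher", cutoffs = 10^-(3:8),
                   seed = 1L, out_dir = ".")
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (is.null(config$reads_a))
    stop("config must name reads_a (MeDIP-seq BED for sample A)")
  if (is.null(config$reference) && is.null(config$cpg_table))
    stop("config must name a reference FASTA or a cpg_table TSV")
  for (k in c("reads_a", "reads_b", "mre_a", "mre_b", "reference",
              "cpg_table", "blacklist")) {
    pth <- config[[k]]
    if (!is.null(pth) && !file.exists(pth))
      stop("config path for '", k, "' does not exist: ", pth)
  }
  config$cutoffs <- sort(as.numeric(config$cutoffs), decreasing = TRUE)
  config$model <- match.arg(config$model, c("multinomial", "bernoulli"))
  class(config) <- "pipeline_config"
  config
}

.write_tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  data.table::fwrite(df, path, sep = "\t")
  path
}

#' Run the full allocation and differential-methylation pipeline
#'
#' sites -> matrix -> allocate -> test -> report. Loads or derives the CpG
#' index, builds per-region coverage matrices for each sample, fits the
#' chosen allocation model per region, and (when two samples are given)
#' tests every CpG site for differential methylation with both the allocated
#' counts and the raw comparator. All outputs are plain TSV; a `run_info.txt`
#' echoes the package version and full configuration so a run can be
#' reproduced. Outputs are deterministic for fixed inputs and seed.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @return Invisibly, a list of written file paths plus the in-memory site
#'   tables (`counts_a`, `counts_b`) and, for two-sample runs, the
#'   allocated-count and raw-count pair tables.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  message("[medipcpg] loading CpG sites")
  index <- if (!is.null(config$cpg_table)) {
    read_cpg_table(config$cpg_table)
  } else {
    find_cpg_sites(config$reference, blacklist = config$blacklist)
  }
  if (!is.null(config$blacklist) && !is.null(config$cpg_table)) {
    bl <- read_bed(config$blacklist)
    keep <- rep(TRUE, nrow(index))
    for (r in seq_len(nrow(bl))) {
      keep <- keep & !(index$chrom == bl$chrom[r] &
                         index$pos < bl$end[r] &
                         index$pos + 2L > bl$start[r])
    }
    index <- index[keep, , drop = FALSE]
    rownames(index) <- NULL
    class(index) <- c("cpg_index", "data.frame")
  }
  reads_a <- read_bed(config$reads_a, sample = "A")
  reads_b <- if (!is.null(config$reads_b))
    read_bed(config$reads_b, sample = "B")
  link_dist <- config$link_dist
  if (is.null(link_dist)) {
    lens <- c(reads_a$end - reads_a$start,
              if (!is.null(reads_b)) reads_b$end - reads_b$start)
    link_dist <- if (length(lens)) max(lens) else 1000L
    message("[medipcpg] link_dist defaulted to max read length: ",
            link_dist)
  }
  if (all(is.na(index$region_id)))
    index <- segment_regions(index, link_dist)
  out <- list()
  results <- list(index = index)
  empty_a <- nrow(reads_a) == 0L
  if (empty_a)
    warning("sample A read file is empty; outputs will be all-zero")
  mre_a <- if (!is.null(config$mre_a)) read_bed(config$mre_a)
  counts_a <- allocate_sample(reads_a, index, model = config$model,
                              mre_reads = mre_a, tol = config$tol,
                              max_iter = config$max_iter,
                              min_overlap = config$min_overlap)
  message(sprintf("[medipcpg] sample A: %d reads, %d discarded, %d regions fit",
                  nrow(reads_a), attr(counts_a, "discarded"),
                  length(attr(counts_a, "em_iterations"))))
  if (length(attr(counts_a, "degenerate_regions")))
    message("[medipcpg] degenerate EM fixed point in regions: ",
            paste(attr(counts_a, "degenerate_regions"), collapse = ", "))
  out$counts_a <- .write_tsv(counts_a, config$out_dir, "sites_a.tsv")
  results$counts_a <- counts_a
  if (!is.null(reads_b)) {
    mre_b <- if (!is.null(config$mre_b)) read_bed(config$mre_b)
    counts_b <- allocate_sample(reads_b, index, model = config$model,
                                mre_reads = mre_b, tol = config$tol,
                                max_iter = config$max_iter,
                                min_overlap = config$min_overlap)
    message(sprintf(
      "[medipcpg] sample B: %d reads, %d discarded, %d regions fit",
      nrow(reads_b), attr(counts_b, "discarded"),
      length(attr(counts_b, "em_iterations"))))
    out$counts_b <- .write_tsv(counts_b, config$out_dir, "sites_b.tsv")
    results$counts_b <- counts_b
    if (sum(counts_a$allocated) > 0L && sum(counts_b$allocated) > 0L) {
      tab_alloc <- diff_table(counts_a, counts_b, use = "allocated",
                              method = config$test_method)
      tab_raw <- diff_table(counts_a, counts_b, use = "raw",
                            method = config$test_method)
      out$diff_allocated <- .write_tsv(tab_alloc, config$out_dir,
                                       "diff_allocated.tsv")
      out$diff_raw <- .write_tsv(tab_raw, config$out_dir, "diff_raw.tsv")
      out$report_allocated <- .write_tsv(
        cutoff_report(tab_alloc$p_value, config$cutoffs, nrow(index)),
        config$out_dir, "cutoff_report_allocated.tsv")
      out$report_raw <- .write_tsv(
        cutoff_report(tab_raw$p_value, config$cutoffs, nrow(index)),
        config$out_dir, "cutoff_report_raw.tsv")
      results$diff_allocated <- tab_alloc
      results$diff_raw <- tab_raw
    } else {
      warning("a sample has zero allocated counts; differential test skipped")
    }
  }
  info <- c(sprintf("medipcpg version %s",
                    as.character(utils::packageVersion("medipcpg"))),
            sprintf("link_dist\t%d", as.integer(link_dist)),
            sprintf("n_cpg_sites\t%d", nrow(index)),
            "config:",
            jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                             null = "null", pretty = TRUE))
  writeLines(info, file.path(config$out_dir, "run_info.txt"))
  out$run_info <- file.path(config$out_dir, "run_info.txt")
  results$files <- out
  invisible(results)
}
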