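# Quantification of phylogenetically placed metagenomic reads: filtering,
# library/gene-length/copy-number normalization, virus:host ratios,
# composition comparisons and peptide-overlap statistics.

#' Read filter configuration
#'
#' Thresholds applied to placed reads before quantification. Reads attached
#' to the reference tree by a pendant branch longer than `max_branch_length`
#' substitutions/site are spurious placements (typically a different gene)
#' and are removed; short reads below the minimum post-trimming length are
#' also removed. The e-value cutoff is applied upstream in the homology
#' search that recruits reads and is recorded here as provenance only.
#'
#' @param max_branch_length Maximum pendant branch length, default 2.0.
#' @param min_length_nt Minimum read length for nucleotide-space markers,
#'   default 100 nt.
#' @param min_length_aa Minimum read length for amino-acid-space markers,
#'   default 33 aa.
#' @param max_evalue_exp Recorded e-value exponent cutoff of the upstream
#'   search (e < 10^x), default -5.
#'
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(max_branch_length = 2.0, min_length_nt = 100,
                          min_length_aa = 33, max_evalue_exp = -5) {
  v <- c(max_branch_length, min_length_nt, min_length_aa, max_evalue_exp)
  if (any(!is.finite(v))) stop("all thresholds must be finite")
  structure(list(max_branch_length = max_branch_length,
                 min_length_nt = min_length_nt,
                 min_length_aa = min_length_aa,
                 max_evalue_exp = max_evalue_exp),
            class = "filter_config")
}

#' Filter placed reads
#'
#' Removes reads whose pendant branch length exceeds the threshold or whose
#' length falls below the minimum. Paired reads placed as one are collapsed
#' by read id first (the `paired` column, if present, marks them). The kept
#' and removed sets partition the deduplicated input exactly.
#'
#' @param reads Data frame with columns `read_id`, `gene`, `clade`,
#'   `branch_length`, `read_len_nt`, `sample_id`, and optionally `paired`.
#' @param cfg A [filter_config()]. The nucleotide-length minimum is applied
#'   to `read_len_nt`.
#'
#' @return List with `kept`, `removed` (data frames) and `removed_fraction`.
#' @export
filter_reads <- function(reads, cfg = filter_config()) {
  req <- c("read_id", "gene", "clade", "branch_length", "read_len_nt",
           "sample_id")
  if (!all(req %in% names(reads)))
    stop("missing columns: ", paste(setdiff(req, names(reads)), collapse = ", "))
  if (any(reads$branch_length < 0)) stop("branch lengths must be non-negative")
  # one placement per read: paired mates were aligned and placed together
  reads <- reads[!duplicated(reads[c("sample_id", "read_id")]), , drop = FALSE]
  bad <- reads$branch_length > cfg$max_branch_length |
    reads$read_len_nt < cfg$min_length_nt
  list(kept = reads[!bad, , drop = FALSE],
       removed = reads[bad, , drop = FALSE],
       removed_fraction = if (nrow(reads)) mean(bad) else 0)
}

#' Normalized, copy-number-corrected abundance table
#'
#' Counts kept reads per (sample, gene, clade) and normalizes:
#' abundance = count / (library_total * gene_length) * 100, then divided by
#' the clade's marker copy number so multi-copy markers (e.g. the rRNA ITS
#' in some cyanobacterial clades) do not inflate apparent abundance.
#'
#' @param reads Kept reads (see [filter_reads()]).
#' @param samples Data frame with `sample_id` and `library_size` (total
#'   sequences in each metagenome); extra columns such as `depth_m` or
#'   `size_fraction` pass through unused.
#' @param genes Data frame with `gene`, `ref_length` (reference alignment
#'   length) and `length_unit` ("aa" or "nt", recorded to prevent silent
#'   unit mixing).
#' @param copy_numbers Optional data frame with `gene`, `clade`,
#'   `copy_number` (>= 1); clades not listed default to 1 copy.
#'
#' @return Data frame of class `abundance_table` with columns `sample_id`,
#'   `gene`, `clade`, `count` (raw, integer), `copy_number`, `abundance`.
#' @export
normalize_abundance <- function(reads, samples, genes, copy_numbers = NULL) {
  missing_s <- setdiff(unique(reads$sample_id), samples$sample_id)
  missing_g <- setdiff(unique(reads$gene), genes$gene)
  if (length(missing_s) || length(missing_g))
    stop("missing metadata for ",
         paste(c(if (length(missing_s)) paste("samples:", paste(missing_s, collapse = ", ")),
                 if (length(missing_g)) paste("genes:", paste(missing_g, collapse = ", "))),
               collapse = "; "))
  if (any(samples$library_size <= 0)) stop("library sizes must be positive")
  if (any(genes$ref_length <= 0)) stop("gene lengths must be positive")
  tab <- as.data.frame(table(sample_id = reads$sample_id, gene = reads$gene,
                             clade = reads$clade), stringsAsFactors = FALSE)
  names(tab)[4] <- "count"
  tab <- tab[tab$count > 0, , drop = FALSE]
  tab$library_size <- samples$library_size[match(tab$sample_id, samples$sample_id)]
  tab$ref_length <- genes$ref_length[match(tab$gene, genes$gene)]
  tab$copy_number <- 1
  if (!is.null(copy_numbers)) {
    if (any(copy_numbers$copy_number < 1)) stop("copy numbers must be >= 1")
    i <- match(paste(tab$gene, tab$clade), paste(copy_numbers$gene, copy_numbers$clade))
    tab$copy_number[!is.na(i)] <- copy_numbers$copy_number[i[!is.na(i)]]
  }
  tab$abundance <- tab$count / (tab$library_size * tab$ref_length) * 100 /
    tab$copy_number
  tab <- tab[order(tab$sample_id, tab$gene, tab$clade),
             c("sample_id", "gene", "clade", "count", "copy_number", "abundance")]
  rownames(tab) <- NULL
  class(tab) <- c("abundance_table", "data.frame")
  tab
}

#' Virus-to-host marker ratio
#'
#' Ratio of the length-normalized abundance of a viral marker gene (summed
#' over viral clades) to that of a host marker gene (summed over host
#' clades) in one sample — e.g. cyanophage DNA polymerase over
#' cyanobacterial rpoB. Length normalization makes the two markers
#' comparable despite different reference lengths.
#'
#' @param table An `abundance_table` from [normalize_abundance()].
#' @param virus_gene,host_gene Gene names.
#' @param sample Sample id.
#'
#' @return The ratio, or `NA` with attribute `undefined = TRUE` when the
#'   host abundance is zero (absence of host reads does not mean an
#'   infinite ratio).
#' @export
virus_host_ratio <- function(table, virus_gene, host_gene, sample) {
  sl <- table[table$sample_id == sample, , drop = FALSE]
  v <- sum(sl$abundance[sl$gene == virus_gene])
  h <- sum(sl$abundance[sl$gene == host_gene])
  if (h <= 0) {
    r <- NA_real_
    attr(r, "undefined") <- TRUE
    return(r)
  }
  v / h
}

#' Clade composition fractions for one gene and sample
#'
#' @param table An `abundance_table`.
#' @param gene Gene name.
#' @param sample Sample id.
#'
#' @return Named numeric vector of fractions summing to 1.
#' @export
composition_fractions <- function(table, gene, sample) {
  sl <- table[table$sample_id == sample & table$gene == gene, , drop = FALSE]
  if (nrow(sl) == 0 || sum(sl$abundance) <= 0)
    stop("no abundance for gene ", gene, " in sample ", sample)
  stats::setNames(sl$abundance / sum(sl$abundance), sl$clade)
}

#' Compare clade proportions between two samples
#'
#' Matches clade proportions of one gene across two samples (clades absent
#' from one sample get proportion 0) and summarizes the departure from the
#' 1:1 line.
#'
#' @param table An `abundance_table`.
#' @param gene Gene name.
#' @param sample_a,sample_b Sample ids, both present for `gene`.
#'
#' @return List with `pairs` (data frame: clade, prop_a, prop_b),
#'   `max_abs_deviation`, and `rms_deviation` from the 1:1 line.
#' @export
compare_proportions <- function(table, gene, sample_a, sample_b) {
  fa <- composition_fractions(table, gene, sample_a)
  fb <- composition_fractions(table, gene, sample_b)
  clades <- sort(union(names(fa), names(fb)))
  pa <- ifelse(clades %in% names(fa), fa[clades], 0)
  pb <- ifelse(clades %in% names(fb), fb[clades], 0)
  dev <- pa - pb
  list(pairs = data.frame(clade = clades, prop_a = as.numeric(pa),
                          prop_b = as.numeric(pb), row.names = NULL),
       max_abs_deviation = max(abs(dev)),
       rms_deviation = sqrt(mean(dev^2)))
}

#' Peptide sharing between samples
#'
#' For a focal sample, computes the fraction of its peptides found in each
#' other sample, and the Venn-style partition of focal peptides by the
#' exact subset of other samples that also contain them (partition
#' fractions sum to 1).
#'
#' @param obs Data frame with columns `sample_id`, `peptide`, and
#'   optionally `taxon`.
#' @param focal_sample Focal sample id.
#' @param other_samples Character vector of comparison sample ids.
#' @param taxon_filter Optional taxon label; restricts all sets to peptides
#'   annotated with that taxon.
#'
#' @return List with `shared` (named fractions, one per other sample) and
#'   `partition` (data frame: subset label, count, fraction).
#' @export
peptide_overlap <- function(obs, focal_sample, other_samples,
                            taxon_filter = NULL) {
  if (!is.null(taxon_filter)) {
    if (!"taxon" %in% names(obs)) stop("no taxon column to filter on")
    obs <- obs[obs$taxon == taxon_filter, , drop = FALSE]
  }
  sets <- lapply(c(focal_sample, other_samples), function(s)
    unique(obs$peptide[obs$sample_id == s]))
  names(sets) <- c(focal_sample, other_samples)
  focal <- sets[[focal_sample]]
  if (length(focal) == 0) stop("focal sample has no peptides after filtering")
  shared <- vapply(other_samples, function(s)
    mean(focal %in% sets[[s]]), numeric(1))
  membership <- vapply(other_samples, function(s) focal %in% sets[[s]],
                       logical(length(focal)))
  membership <- matrix(membership, nrow = length(focal))
  label <- apply(membership, 1, function(m) {
    if (!any(m)) "unique" else paste(other_samples[m], collapse = "&")
  })
  counts <- table(label)
  list(shared = shared,
       partition = data.frame(subset = names(counts),
                              count = as.integer(counts),
                              fraction = as.numeric(counts) / length(focal),
                              row.names = NULL))
}
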