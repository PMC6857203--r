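# Readers/writers for the standard formats and the run configuration.
# Coordinate convention: VCF/GFF/TSV are 1-based inclusive on disk; all
# internal interval arithmetic is 0-based half-open, and the conversion
# happens only in this file.

#' Convert disk coordinates (1-based inclusive) to internal (0-based half-open)
#' @param start,end 1-based inclusive interval.
#' @return List with `start`, `end` (0-based half-open).
#' @export
to_internal_coords <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  list(start = start - 1L, end = end)
}

#' Convert internal coordinates (0-based half-open) back to disk (1-based inclusive)
#' @param start,end 0-based half-open interval.
#' @return List with `start`, `end` (1-based inclusive).
#' @export
to_disk_coords <- function(start, end) {
  stopifnot(all(start >= 0), all(end > start))
  list(start = start + 1L, end = end)
}

#' Read a sample-to-population map
#'
#' Two-column TSV without header: sample, population (`K` or `W`).
#'
#' @param path File path.
#' @return Named character vector (population per sample).
#' @export
read_popmap <- function(path) {
  df <- read.delim(path, header = FALSE, col.names = c("sample", "pop"),
                   colClasses = "character")
  if (anyDuplicated(df$sample)) stop("duplicate sample in population map")
  setNames(df$pop, df$sample)
}

#' Construct a variant table
#'
#' Genotypes are allele dosages in `{0, 1, 2}` with `NA` for missing;
#' positions are 1-based and must be strictly increasing within scaffold.
#'
#' @param sample_ids Character vector.
#' @param pop Population label (`"K"`/`"W"`) per sample.
#' @param scaffold Scaffold id per site.
#' @param pos 1-based position per site.
#' @param dos Dosage matrix, samples x sites.
#' @param ref,alt Allele symbols per site.
#' @param contig_lengths Optional named vector of scaffold lengths.
#' @return A `variant_table`.
#' @export
variant_table <- function(sample_ids, pop, scaffold, pos, dos, ref, alt,
                          contig_lengths = NULL) {
  dos <- as.matrix(dos)
  stopifnot(length(sample_ids) == nrow(dos), length(pop) == nrow(dos),
            length(scaffold) == ncol(dos), length(pos) == ncol(dos),
            length(ref) == ncol(dos), length(alt) == ncol(dos))
  for (sc in unique(scaffold)) {
    p <- pos[scaffold == sc]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("positions not strictly increasing on scaffold ", sc)
  }
  if (!all(dos %in% c(0, 1, 2, NA))) stop("dosages must be 0, 1, 2 or NA")
  structure(list(sample_ids = as.character(sample_ids), pop = as.character(pop),
                 scaffold = as.character(scaffold), pos = as.integer(pos),
                 dos = dos, ref = as.character(ref), alt = as.character(alt),
                 contig_lengths = contig_lengths),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("<variant_table> ", length(x$sample_ids), " samples (",
      sum(x$pop == "K"), " K / ", sum(x$pop == "W"), " W), ",
      ncol(x$dos), " biallelic SNPs on ", length(unique(x$scaffold)),
      " scaffold(s)\n", sep = "")
  invisible(x)
}

#' Number of sites in a variant table
#' @param vt A `variant_table`.
#' @return Integer site count.
#' @export
n_sites <- function(vt) ncol(vt$dos)

# Subset a variant table by site index (keeps all samples).
vt_subset <- function(vt, idx) {
  variant_table(vt$sample_ids, vt$pop, vt$scaffold[idx], vt$pos[idx],
                vt$dos[, idx, drop = FALSE], vt$ref[idx], vt$alt[idx],
                vt$contig_lengths)
}

#' Read genotypes from a VCF file
#'
#' Keeps only biallelic SNP records; missing and half-called genotypes are
#' recorded as `NA`. Every VCF sample must appear in the population map.
#'
#' @param path VCF 4.x file (plain text or gzipped).
#' @param pop_map Named vector from [read_popmap()].
#' @return A `variant_table`.
#' @export
read_variant_table <- function(path, pop_map) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) stop("no records in VCF")
  samples <- colnames(vcf@gt)[-1]
  unknown <- setdiff(samples, names(pop_map))
  if (length(unknown))
    stop("samples missing from population map: ",
         paste(unknown, collapse = ", "))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  gt <- vcf@gt[keep, -1, drop = FALSE]
  # dosage with NA for missing or half-called genotypes
  allele <- function(x, i) substr(x, c(1, 3)[i], c(1, 3)[i])
  gsub_phase <- function(x) gsub("|", "/", x, fixed = TRUE)
  dos <- apply(gt, 2, function(col) {
    col <- gsub_phase(col)
    col <- sub(":.*$", "", col)
    a1 <- substr(col, 1, 1)
    a2 <- substr(col, 3, 3)
    d <- suppressWarnings(as.integer(a1) + as.integer(a2))
    d[!a1 %in% c("0", "1") | !a2 %in% c("0", "1")] <- NA_integer_
    d
  })
  dos <- matrix(dos, ncol = length(samples),
                dimnames = list(NULL, samples))
  meta <- vcf@meta
  cl <- NULL
  ctg <- grep("^##contig", meta, value = TRUE)
  if (length(ctg)) {
    ids <- sub(".*ID=([^,>]+).*", "\\1", ctg)
    lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", ctg)))
    cl <- setNames(lens, ids)
  }
  variant_table(samples, unname(pop_map[samples]),
                fix[keep, "CHROM"], as.integer(fix[keep, "POS"]),
                t(dos), ref[keep], alt[keep], cl)
}

#' Write a variant table as VCF 4.2
#'
#' Plain-text writer emitting unphased diploid genotypes (`0/0`, `0/1`,
#' `1/1`, `./.`) and `##contig` header lines when lengths are known.
#'
#' @param vt A `variant_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=divergesim",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(vt$contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(vt$contig_lengths),
                          as.integer(vt$contig_lengths)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", vt$sample_ids), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(n_sites(vt)), function(j) {
    d <- vt$dos[, j]
    g <- ifelse(is.na(d), "./.", gt_code[d + 1])
    paste(c(vt$scaffold[j], vt$pos[j], ".", vt$ref[j], vt$alt[j], ".", "PASS",
            ".", "GT", g), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a scaffold-to-chromosome map
#'
#' TSV columns: scaffold, chromosome, class (`autosome`/`Z`/`unassigned`),
#' ordering index.
#'
#' @param path File path.
#' @return Data frame (class `scaffold_map`).
#' @export
read_scaffold_map <- function(path) {
  df <- read.delim(path, header = FALSE,
                   col.names = c("scaffold", "chrom", "class", "index"))
  scaffold_map(df)
}

#' @rdname read_scaffold_map
#' @param df Data frame with the four map columns.
#' @export
scaffold_map <- function(df) {
  stopifnot(all(c("scaffold", "chrom", "class", "index") %in% names(df)))
  if (anyDuplicated(df$scaffold)) stop("scaffold appears twice in map")
  bad <- setdiff(unique(df$class), c("autosome", "Z", "W", "unassigned"))
  if (length(bad)) stop("unknown chromosome class: ", paste(bad, collapse = ", "))
  structure(df, class = c("scaffold_map", "data.frame"))
}

scaffold_class <- function(map, scaffolds) {
  cl <- map$class[match(scaffolds, map$scaffold)]
  miss <- is.na(cl)
  if (any(miss)) {
    warning("scaffold(s) absent from map treated as unassigned: ",
            paste(unique(scaffolds[miss]), collapse = ", "))
    cl[miss] <- "unassigned"
  }
  cl
}

#' Read gene models (CDS intervals) from a GFF3 file
#'
#' CDS features are grouped by their `Parent` (or `gene_id`) attribute and
#' overlapping intervals merged per gene. A gene with CDS on more than one
#' scaffold is dropped with a warning.
#'
#' @param path GFF3 file.
#' @return A `gene_annotation`: data frame with one row per CDS interval
#'   (columns gene_id, scaffold, strand, start, end; 1-based inclusive,
#'   merged).
#' @export
read_gene_annotations <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "CDS"]
    gid <- if (!is.null(gr$Parent) && any(lengths(gr$Parent) > 0)) {
      vapply(as.list(gr$Parent), function(p) if (length(p)) p[[1]] else NA_character_,
             character(1))
    } else if (!is.null(gr$gene_id)) {
      as.character(gr$gene_id)
    } else if (!is.null(gr$ID)) as.character(gr$ID) else
      stop("CDS features lack Parent/gene_id attributes")
    df <- data.frame(gene_id = gid,
                     scaffold = as.character(GenomicRanges::seqnames(gr)),
                     strand = as.character(GenomicRanges::strand(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr))
  } else {
    raw <- read.delim(path, header = FALSE, comment.char = "#",
                      colClasses = "character")
    raw <- raw[raw[[3]] == "CDS", , drop = FALSE]
    gid <- sub(".*(?:Parent|gene_id)=([^;]+).*", "\\1", raw[[9]])
    df <- data.frame(gene_id = gid, scaffold = raw[[1]], strand = raw[[7]],
                     start = as.integer(raw[[4]]), end = as.integer(raw[[5]]))
  }
  gene_annotation(df)
}

#' @rdname read_gene_annotations
#' @param df Data frame with columns gene_id, scaffold, strand, start, end
#'   (1-based inclusive, possibly overlapping).
#' @export
gene_annotation <- function(df) {
  stopifnot(all(c("gene_id", "scaffold", "start", "end") %in% names(df)))
  if (is.null(df$strand)) df$strand <- "+"
  if (any(df$end < df$start)) stop("CDS interval with end < start")
  multi <- tapply(df$scaffold, df$gene_id, function(s) length(unique(s)) > 1)
  if (any(multi)) {
    bad <- names(multi)[multi]
    warning("gene(s) with CDS on multiple scaffolds dropped: ",
            paste(bad, collapse = ", "))
    df <- df[!df$gene_id %in% bad, , drop = FALSE]
  }
  # merge overlapping intervals per gene (0-based half-open internally)
  out <- do.call(rbind, lapply(split(df, df$gene_id), function(g) {
    ic <- to_internal_coords(g$start, g$end)
    o <- order(ic$start)
    s <- ic$start[o]; e <- ic$end[o]
    ms <- s[1]; me <- e[1]; rs <- c(); re <- c()
    for (i in seq_along(s)[-1]) {
      if (s[i] <= me) me <- max(me, e[i])
      else { rs <- c(rs, ms); re <- c(re, me); ms <- s[i]; me <- e[i] }
    }
    rs <- c(rs, ms); re <- c(re, me)
    dc <- to_disk_coords(rs, re)
    data.frame(gene_id = g$gene_id[1], scaffold = g$scaffold[1],
               strand = g$strand[1], start = dc$start, end = dc$end)
  }))
  rownames(out) <- NULL
  structure(out, class = c("gene_annotation", "data.frame"))
}

#' Read a gene-to-GO annotation table and apply the category grouping rules
#'
#' TSV columns: gene, GO category id, domain (`biological_process` or
#' `cellular_component`). Within each domain, categories with fewer than 50
#' member genes are merged into a single `small` category; universe genes
#' with no annotation in a domain are assigned to `uncharacterized`.
#'
#' @param path File path.
#' @param universe Character vector of all genes (defaults to the genes in
#'   the table).
#' @param min_genes Grouping threshold (50).
#' @return A `go_annotation`: list of per-domain membership lists
#'   (`category -> genes`).
#' @export
read_go_table <- function(path, universe = NULL, min_genes = 50) {
  df <- read.delim(path, header = FALSE,
                   col.names = c("gene", "category", "domain"),
                   colClasses = "character")
  go_annotation(df, universe = universe, min_genes = min_genes)
}

#' @rdname read_go_table
#' @param df Data frame with columns gene, category, domain.
#' @export
go_annotation <- function(df, universe = NULL, min_genes = 50) {
  stopifnot(all(c("gene", "category", "domain") %in% names(df)))
  if (is.null(universe)) universe <- unique(df$gene)
  domains <- sort(unique(df$domain))
  out <- lapply(domains, function(dm) {
    d <- unique(df[df$domain == dm, c("gene", "category")])
    memb <- split(d$gene, d$category)
    sizes <- lengths(memb)
    small <- names(sizes)[sizes < min_genes]
    kept <- memb[setdiff(names(memb), small)]
    if (length(small))
      kept$small <- sort(unique(unlist(memb[small], use.names = FALSE)))
    annotated <- unique(d$gene)
    unchar <- setdiff(universe, annotated)
    if (length(unchar)) kept$uncharacterized <- sort(unchar)
    kept
  })
  names(out) <- domains
  structure(list(domains = out, universe = universe, min_genes = min_genes),
            class = "go_annotation")
}

#' @export
print.go_annotation <- function(x, ...) {
  for (dm in names(x$domains))
    cat("<go_annotation> ", dm, ": ", length(x$domains[[dm]]),
        " categories over ", length(x$universe), " genes\n", sep = "")
  invisible(x)
}

#' Default run configuration
#'
#' All tunables of the two pipelines with their defaults: mutation rate
#' 0.8e-8 per site per generation, generation time 2.5 years, 10+10 diploid
#' samples, 10-kb loci, model-choice tolerance 0.005 and estimation
#' tolerance 0.002 (study scale), 50-kb windows with a 25-kb minimum, the
#' 95th/5th percentile outlier rules, and the locus/simulation filters.
#'
#' @return Named list (class `run_config`).
#' @export
default_config <- function() {
  structure(list(
    mu = 0.8e-8, g = 2.5,
    n_K = 20, n_W = 20,           # haplotypes
    locus_length = 1e4,
    n_loci = 143,
    priors = default_priors(),
    tolerance_model_choice = 0.005,
    tolerance_estimate = 0.002,
    n_networks = 50,
    window_size = 50000, window_min_length = 25000,
    fst_percentile = 0.95, d_high_percentile = 0.95, d_low_percentile = 0.05,
    locus_fst_max = 0.159, locus_d_range = c(0, 1),
    locus_missing_individual = 0.40, locus_missing_mean = 0.30,
    locus_min_distance = 5e5, scaffold_min_coverage = 0.80,
    snp_max_missing = 0.10, snp_min_maf = 0.05,
    snp_window = 10, snp_window_max = 3,
    r2_type = "haplotype",        # simulated reference tables are phased
    seed = 1
  ), class = "run_config")
}

#' Read a YAML run configuration
#'
#' Values in the file override the defaults from [default_config()];
#' prior entries are merged per parameter.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  # YAML 1.1 only recognizes scientific notation with an explicit sign
  # ("1.0e+5"); tolerate the common unsigned form by coercing numeric-looking
  # strings
  coerce_num <- function(x) {
    if (is.list(x)) return(lapply(x, coerce_num))
    if (is.character(x) && length(x) == 1 &&
        grepl("^[+-]?[0-9.]+([eE][+-]?[0-9]+)?$", x)) return(as.numeric(x))
    x
  }
  user <- coerce_num(user)
  for (nm in names(user)) {
    if (nm == "priors") {
      for (pn in names(user$priors)) cfg$priors[[pn]] <-
          utils::modifyList(cfg$priors[[pn]], user$priors[[pn]])
    } else cfg[[nm]] <- user[[nm]]
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$mu > 0, cfg$g > 0, cfg$n_K > 0, cfg$n_W > 0,
            cfg$locus_length > 0,
            cfg$tolerance_model_choice > 0, cfg$tolerance_model_choice <= 1,
            cfg$tolerance_estimate > 0, cfg$tolerance_estimate <= 1,
            cfg$window_size > 0)
  cfg
}
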