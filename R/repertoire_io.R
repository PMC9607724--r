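# repertoire_io: on-disk formats (AIRR TSV, 10x contig CSV, germline FASTA,
# per-cell tables) and assembly of per-barcode chains into cell records.
#
# A repertoire is a tibble with one row per cell ("cell table"). Heavy chain
# fields are prefixed h_, light chain fields l_. CDR3 amino-acid strings
# follow the junction-style convention: the conserved C and W/F residues are
# retained (CIKDILPGGADSW-style), and identity computations use that string.

CHAIN_COLUMNS <- c("cell_id", "locus", "v_gene", "d_gene", "j_gene", "v_call",
                   "cdr3_aa", "junction_nt", "junction_start", "seq_nt",
                   "fwr4_nt", "isotype", "productive")

CELL_COLUMNS <- c(
  "cell_id", "donor_id", "dataset_id", "sort_label",
  "h_v_gene", "h_d_gene", "h_j_gene", "h_v_call", "h_cdr3_aa",
  "h_junction_nt", "h_junction_start", "h_seq_nt", "h_fwr4_nt",
  "h_isotype", "h_productive",
  "l_locus", "l_v_gene", "l_j_gene", "l_v_call", "l_cdr3_aa",
  "l_junction_nt", "l_junction_start", "l_seq_nt", "l_fwr4_nt",
  "l_productive",
  "shm_count", "cell_class", "clonotype_id")

strip_allele <- function(call) sub("\\*.*$", "", call)

parse_flag <- function(x) {
  toupper(as.character(x)) %in% c("T", "TRUE", "1", "YES")
}

#' Read an IMGT-style germline V/D/J reference FASTA
#'
#' Headers must encode `gene*allele` (e.g. `>IGHV3-9*01`). The segment type
#' (V, D or J) and locus (IGH, IGK, IGL) are inferred from the gene name.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `gene`, `allele`, `locus`, `segment`, `seq`,
#'   and annotation columns `v_tail` (junction-region length at the V 3' end)
#'   and `fwr4_start` (1-based FWR4 start within J genes), `NA` unless the
#'   reference carries them (the simulator's references do).
#' @export
read_germline_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) {
    rc_abort("germline reference is empty", "missing_reference")
  }
  headers <- sub("\\s.*$", "", names(seqs))
  gene <- strip_allele(headers)
  allele <- ifelse(grepl("\\*", headers), sub("^.*\\*", "", headers), "01")
  bad <- !grepl("^IG[HKL][VDJ]", gene)
  if (any(bad)) {
    rc_abort(paste0("cannot parse gene name from header: ", headers[bad][1]),
             "malformed_header")
  }
  key <- paste(gene, allele)
  if (anyDuplicated(key)) {
    rc_abort(paste0("duplicated (gene, allele): ", key[duplicated(key)][1]),
             "duplicate_gene")
  }
  tibble(
    gene = gene,
    allele = allele,
    locus = substr(gene, 1, 3),
    segment = substr(gene, 4, 4),
    seq = unname(toupper(as.character(seqs))),
    v_tail = NA_integer_,
    fwr4_start = NA_integer_
  )
}

#' Read AIRR Rearrangement TSV into chain annotations
#'
#' Nonproductive rows and rows without a junction are skipped; the number of
#' skipped rows is attached as attribute `n_skipped`.
#'
#' @param path Path to an AIRR Rearrangement TSV.
#' @return A tibble of chain annotations keyed by `cell_id`.
#' @export
read_airr_rearrangements <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  required <- c("cell_id", "locus", "v_call", "j_call", "junction",
                "junction_aa", "sequence", "productive")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    rc_abort(paste0("missing AIRR column(s): ", paste(missing, collapse = ", ")),
             "missing_column")
  }
  keep <- parse_flag(df$productive) &
    !is.na(df$junction_aa) & nzchar(df$junction_aa) &
    !is.na(df$junction) & nzchar(df$junction)
  n_skipped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  get_col <- function(nm) if (nm %in% names(df)) df[[nm]] else NA_character_
  out <- tibble(
    cell_id = df$cell_id,
    locus = df$locus,
    v_gene = strip_allele(df$v_call),
    d_gene = strip_allele(get_col("d_call")),
    j_gene = strip_allele(df$j_call),
    v_call = df$v_call,
    cdr3_aa = df$junction_aa,
    junction_nt = df$junction,
    junction_start = suppressWarnings(as.integer(get_col("junction_start"))),
    seq_nt = df$sequence,
    fwr4_nt = get_col("fwr4"),
    isotype = get_col("c_call"),
    productive = TRUE
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a 10x filtered contig annotation CSV into chain annotations
#'
#' Rows that are not full length, not productive, not an IG chain (e.g.
#' `Multi`), or have no CDR3 are skipped and counted.
#'
#' @param path Path to a `filtered_contig_annotations.csv`-style file.
#' @return A tibble of chain annotations keyed by `cell_id` (the barcode).
#' @export
read_10x_contigs <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  required <- c("barcode", "chain", "v_gene", "j_gene", "cdr3", "cdr3_nt",
                "full_length", "productive")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    rc_abort(paste0("missing 10x column(s): ", paste(missing, collapse = ", ")),
             "missing_column")
  }
  keep <- df$chain %in% c("IGH", "IGK", "IGL") &
    parse_flag(df$full_length) & parse_flag(df$productive) &
    !is.na(df$cdr3) & nzchar(df$cdr3) & df$cdr3 != "None"
  n_skipped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  get_col <- function(nm) if (nm %in% names(df)) df[[nm]] else NA_character_
  out <- tibble(
    cell_id = df$barcode,
    locus = df$chain,
    v_gene = strip_allele(df$v_gene),
    d_gene = strip_allele(get_col("d_gene")),
    j_gene = strip_allele(df$j_gene),
    v_call = df$v_gene,
    cdr3_aa = df$cdr3,
    junction_nt = df$cdr3_nt,
    junction_start = NA_integer_,
    seq_nt = get_col("sequence"),
    fwr4_nt = get_col("fwr4"),
    isotype = get_col("c_gene"),
    productive = TRUE
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Assemble chain annotations into paired cell records
#'
#' Keeps only barcodes with exactly one productive heavy (IGH) and exactly one
#' productive light (IGK/IGL) chain; everything else is dropped and tallied
#' (attribute `dropped`: named counts for `multiplet` and `unpaired`).
#'
#' @param chains Chain annotation tibble from [read_airr_rearrangements()] or
#'   [read_10x_contigs()].
#' @param donor_id,dataset_id Metadata applied to every assembled cell.
#' @param sort_label Optional flow-sort label (default `"unknown"`).
#' @return A cell table (one row per cell).
#' @export
assemble_cells <- function(chains, donor_id, dataset_id,
                           sort_label = "unknown") {
  stopifnot(nzchar(donor_id))
  heavy <- chains[chains$locus == "IGH", , drop = FALSE]
  light <- chains[chains$locus %in% c("IGK", "IGL"), , drop = FALSE]
  nh <- table(heavy$cell_id)
  nl <- table(light$cell_id)
  barcodes <- unique(chains$cell_id)
  h1 <- names(nh)[nh == 1]
  l1 <- names(nl)[nl == 1]
  keep <- intersect(h1, l1)
  multiplet <- union(names(nh)[nh > 1], names(nl)[nl > 1])
  dropped <- c(multiplet = length(multiplet),
               unpaired = length(barcodes) - length(keep) - length(multiplet))
  # preserve first-appearance barcode order
  keep <- barcodes[barcodes %in% keep]
  h <- heavy[match(keep, heavy$cell_id), , drop = FALSE]
  l <- light[match(keep, light$cell_id), , drop = FALSE]
  cells <- tibble(
    cell_id = keep,
    donor_id = donor_id,
    dataset_id = dataset_id,
    sort_label = sort_label,
    h_v_gene = h$v_gene, h_d_gene = h$d_gene, h_j_gene = h$j_gene,
    h_v_call = h$v_call, h_cdr3_aa = h$cdr3_aa,
    h_junction_nt = h$junction_nt, h_junction_start = h$junction_start,
    h_seq_nt = h$seq_nt, h_fwr4_nt = h$fwr4_nt,
    h_isotype = h$isotype, h_productive = h$productive,
    l_locus = l$locus, l_v_gene = l$v_gene, l_j_gene = l$j_gene,
    l_v_call = l$v_call, l_cdr3_aa = l$cdr3_aa,
    l_junction_nt = l$junction_nt, l_junction_start = l$junction_start,
    l_seq_nt = l$seq_nt, l_fwr4_nt = l$fwr4_nt,
    l_productive = l$productive,
    shm_count = NA_integer_,
    cell_class = "unset",
    clonotype_id = NA_character_
  )
  attr(cells, "dropped") <- dropped
  cells
}

per_cell_col_types <- function() {
  readr::cols(
    h_junction_start = "i", l_junction_start = "i", shm_count = "i",
    h_productive = "l", l_productive = "l",
    .default = "c"
  )
}

#' Write / read the canonical per-cell table
#'
#' The per-cell TSV is the pipeline's interchange format: one line per cell,
#' all cell-table columns, lossless round trip. `col_map` adapts foreign
#' headers (e.g. from externally deposited per-cell tables) to the canonical
#' names: a named character vector `c(canonical = "foreign")`; the mapping is
#' configuration, not code.
#'
#' @param cells A cell table.
#' @param path File path.
#' @param col_map Optional named character vector renaming foreign columns.
#' @return `read_per_cell_table()` returns a cell table;
#'   `write_per_cell_table()` returns `path` invisibly.
#' @export
write_per_cell_table <- function(cells, path) {
  readr::write_tsv(cells[, CELL_COLUMNS], path, na = "")
  invisible(path)
}

#' @rdname write_per_cell_table
#' @export
read_per_cell_table <- function(path, col_map = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, na = "",
                        col_types = readr::cols(.default = "c"))
  if (!is.null(col_map)) {
    hit <- col_map[col_map %in% names(df)]
    names(df)[match(hit, names(df))] <- names(hit)
  }
  missing <- setdiff(c("cell_id", "donor_id"), names(df))
  if (length(missing) > 0) {
    rc_abort(paste0("missing per-cell column(s): ",
                    paste(missing, collapse = ", ")), "missing_column")
  }
  for (col in setdiff(CELL_COLUMNS, names(df))) {
    df[[col]] <- NA_character_
  }
  df <- df[, CELL_COLUMNS]
  for (col in c("h_junction_start", "l_junction_start", "shm_count")) {
    df[[col]] <- as.integer(df[[col]])
  }
  for (col in c("h_productive", "l_productive")) {
    df[[col]] <- as.logical(df[[col]])
  }
  df$cell_class[is.na(df$cell_class)] <- "unset"
  dup <- unique(df$cell_id[duplicated(df$cell_id)])
  if (length(dup) > 0) {
    donors <- unique(df$donor_id[df$cell_id %in% dup])
    if (length(donors) > 1) {
      rc_abort(paste0("cell_id seen under multiple donors: ", dup[1]),
               "inconsistent_donor")
    }
  }
  as_tibble(df)
}
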