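#' Paired synchronous tumor coding-variant fixture
#'
#' The 23 paired synchronous bilateral Wilms tumor sets with matched germline
#' DNA, transcribed from the published per-pair table: blood germline
#' variant(s), somatic coding variants of the right and left tumors, the
#' shared-variant entry, the adjacent non-diseased kidney 11p15.5 status, and
#' whether blood H19/ICR1 methylation exceeded 2 SD of the control mean.
#'
#' Variant list entries are `GENE` or `GENE:p.X`; [parse_variant_list()]
#' splits them. Gene-only entries carry no protein change and never match
#' across tumors under [shared_coding()].
#'
#' @return data.frame with 23 rows and columns `patient_id`,
#'   `germline_variants`, `somatic_right`, `somatic_left`, `shared_variants`,
#'   `shared_status`, `adjacent_kidney`, `blood_gom`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_paired_somatic.tsv",
                      package = "bwtmosaic", mustWork = TRUE)
  df <- read_tsv(path)
  if (nrow(df) != 23L) {
    stop_validation("paired-somatic fixture must have 23 rows, got %d",
                    nrow(df))
  }
  required <- c("patient_id", "germline_variants", "somatic_right",
                "somatic_left", "shared_variants", "shared_status",
                "adjacent_kidney", "blood_gom")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop_validation("fixture missing columns: %s",
                                       paste(missing, collapse = ", "))
  df$blood_gom <- df$blood_gom == "Yes"
  df
}

#' Paired-tumor shared noncoding variant fixture
#'
#' The 15 whole-genome-sequenced synchronous pairs: per-tumor noncoding
#' somatic variant totals, the shared noncoding count, the pair's 11p15.5
#' status, and predisposing germline variant genes (empty when none was
#' identified). `cnv_similarity` encodes the one pair reported to have a
#' nearly identical genome-wide copy-number profile (0.95) and is NA for all
#' others, where no profile comparison was printed.
#'
#' @return data.frame with 15 rows.
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_shared_noncoding.tsv",
                      package = "bwtmosaic", mustWork = TRUE)
  df <- read_tsv(path)
  if (nrow(df) != 15L) {
    stop_validation("shared-noncoding fixture must have 15 rows, got %d",
                    nrow(df))
  }
  required <- c("patient_id", "tumor1_noncoding", "tumor2_noncoding",
                "shared_noncoding", "icr_status", "germline_genes",
                "cnv_similarity")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop_validation("fixture missing columns: %s",
                                       paste(missing, collapse = ", "))
  df$germline_positive <- !is.na(df$germline_genes) & df$germline_genes != ""
  df
}

#' Parse a comma-separated variant list
#'
#' Entries are `GENE` or `GENE:p.change`. Empty/NA input yields a zero-row
#' set.
#'
#' @param x a single string like `"CTNNB1:p.S45F,TP53"`.
#' @return data.frame with columns `gene` and `protein_change` (NA when the
#'   entry carries no protein change).
#' @export
parse_variant_list <- function(x) {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) {
    return(data.frame(gene = character(), protein_change = character(),
                      stringsAsFactors = FALSE))
  }
  entries <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  entries <- entries[nzchar(entries)]
  parts <- strsplit(entries, ":", fixed = TRUE)
  data.frame(
    gene = toupper(vapply(parts, `[`, "", 1L)),
    protein_change = vapply(parts, function(p) if (length(p) > 1L) p[2] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
}

#' Default Wilms tumor predisposition gene panel
#'
#' The 21 Wilms tumor predisposition genes from the germline analysis; the
#' full 565-gene cancer panel is not reproduced here and can be supplied as a
#' user file (one symbol per line) via [read_gene_panel()].
#'
#' @return character vector of 21 gene symbols.
#' @export
default_panel <- function() {
  path <- system.file("extdata", "wt_panel_genes.txt", package = "bwtmosaic",
                      mustWork = TRUE)
  read_gene_panel(path)
}

#' Read a gene panel file
#' @param path text file, one gene symbol per line; blank lines and `#`
#'   comments ignored.
#' @return uppercased character vector.
#' @export
read_gene_panel <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  toupper(x)
}
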