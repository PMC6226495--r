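#' Construct a validated OTU count table
#'
#' The universal input container for the pipeline: a samples x OTUs matrix of
#' non-negative integer read counts, with per-sample depths (row sums) kept
#' alongside. Count tables on disk are OTU-major (rows = samples, header =
#' OTU ids) but the object is always samples x OTUs internally.
#'
#' @param counts numeric matrix, samples in rows, OTUs in columns. All
#'   entries must be non-negative integers.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   row of `counts`.
#' @param otu_ids character vector of unique OTU identifiers, one per column
#'   of `counts`.
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (integer-valued matrix with dimnames), `sample_ids`, `otu_ids`, and
#'   `depths` (named per-sample read totals).
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(otu_ids)) {
    stop("sample_ids and otu_ids are required (or dimnames on counts)")
  }
  sample_ids <- as.character(sample_ids)
  otu_ids <- as.character(otu_ids)
  if (length(sample_ids) != nrow(counts)) {
    stop("sample_ids length does not match number of rows")
  }
  if (length(otu_ids) != ncol(counts)) {
    stop("otu_ids length does not match number of columns")
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(otu_ids)) stop("duplicate OTU ids")
  if (!is.numeric(counts) || anyNA(counts)) {
    stop("counts must be numeric with no missing values")
  }
  if (any(counts < 0)) stop("negative count in table")
  if (any(counts != round(counts))) stop("non-integer count in table")
  storage.mode(counts) <- "double"   # exact for counts < 2^53
  dimnames(counts) <- list(sample_ids, otu_ids)
  structure(
    list(counts = counts, sample_ids = sample_ids, otu_ids = otu_ids,
         depths = rowSums(counts)),
    class = "otu_table"
  )
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs, depth range [%s, %s]\n",
              length(x$sample_ids), length(x$otu_ids),
              format(min(x$depths)), format(max(x$depths))))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Read an OTU table with taxonomy and sample metadata
#'
#' Reads the three tab-separated inputs of the pipeline and returns validated,
#' index-aligned objects. The count table has a header row of OTU ids and a
#' first column of sample ids. Taxonomy is keyed by `otu_id` with a
#' rank-prefixed lineage string (e.g.
#' `"p__Firmicutes;c__Bacilli;o__Lactobacillales;f__Lactobacillaceae;g__Lactobacillus"`);
#' metadata is keyed by `sample_id` with columns `study`, `platform`,
#' `region`, `breed`, `treatment`. Unparseable numeric cells are an error,
#' never silently zeroed.
#'
#' @param table_path path to the tab-separated count table.
#' @param taxonomy_path path to the tab-separated taxonomy file
#'   (`otu_id`, `lineage`).
#' @param metadata_path path to the tab-separated metadata file.
#' @return A list with elements `table` (an [otu_table]), `taxonomy` (a
#'   taxonomy data frame, see [parse_lineages]), and `metadata` (a data
#'   frame of per-sample covariates).
#' @export
read_otu_table <- function(table_path, taxonomy_path, metadata_path) {
  for (p in c(table_path, taxonomy_path, metadata_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  raw <- utils::read.delim(table_path, header = TRUE, row.names = 1,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  mat <- as.matrix(raw)
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = dimnames(mat)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("unparseable count '%s' at sample '%s', OTU '%s'",
                 mat[bad[1], bad[2]], rownames(mat)[bad[1]],
                 colnames(mat)[bad[2]]))
  }
  if (any(num < 0)) stop("negative count in table")
  tab <- otu_table(num)

  tax <- utils::read.delim(taxonomy_path, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("otu_id", "lineage") %in% names(tax))) {
    stop("taxonomy file must have columns otu_id and lineage")
  }
  if (anyDuplicated(tax$otu_id)) stop("duplicate otu_id in taxonomy")
  missing_tax <- setdiff(tab$otu_ids, tax$otu_id)
  if (length(missing_tax)) {
    stop("taxonomy missing OTUs present in table: ",
         paste(missing_tax, collapse = ", "))
  }
  taxonomy <- parse_lineages(tax$otu_id, tax$lineage)

  meta <- utils::read.delim(metadata_path, header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(meta)) {
    stop("metadata file must have a sample_id column")
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  missing_meta <- setdiff(tab$sample_ids, meta$sample_id)
  if (length(missing_meta)) {
    stop("metadata missing samples present in table: ",
         paste(missing_meta, collapse = ", "))
  }
  list(table = tab,
       taxonomy = taxonomy[match(tab$otu_ids, taxonomy$otu_id), ,
                           drop = FALSE],
       metadata = meta[match(tab$sample_ids, meta$sample_id), , drop = FALSE])
}

#' Parse rank-prefixed lineage strings into a taxonomy table
#'
#' Lineages use semicolon-separated rank prefixes (`p__`, `c__`, `o__`,
#' `f__`, `g__`). A missing or empty rank is recorded as `NA` (unresolved).
#' The display label is the genus when resolved, otherwise the deepest
#' resolved rank prefixed with that rank's name (e.g. `"family Ruminococcaceae"`),
#' mirroring how unresolved taxa are labelled in co-occurrence figures.
#'
#' @param otu_ids character vector of OTU identifiers.
#' @param lineages character vector of lineage strings, same length.
#' @return A data frame of class `taxonomy_map` with columns `otu_id`,
#'   `phylum`, `class`, `order`, `family`, `genus`, `display_label`.
#' @export
parse_lineages <- function(otu_ids, lineages) {
  stopifnot(length(otu_ids) == length(lineages))
  ranks <- c(p = "phylum", c = "class", o = "order", f = "family",
             g = "genus")
  out <- data.frame(otu_id = as.character(otu_ids),
                    phylum = NA_character_, class = NA_character_,
                    order = NA_character_, family = NA_character_,
                    genus = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(lineages)) {
    parts <- strsplit(lineages[i], ";", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    for (part in parts) {
      m <- regmatches(part, regexec("^([pcofg])__(.*)$", part))[[1]]
      if (length(m) == 3 && nzchar(m[3])) out[i, ranks[[m[2]]]] <- m[3]
    }
  }
  out$display_label <- display_labels(out)
  class(out) <- c("taxonomy_map", "data.frame")
  out
}

# genus when resolved, else deepest resolved rank prefixed with its name
display_labels <- function(tax) {
  vapply(seq_len(nrow(tax)), function(i) {
    if (!is.na(tax$genus[i])) return(tax$genus[i])
    for (rk in c("family", "order", "class", "phylum")) {
      if (!is.na(tax[[rk]][i])) return(paste(rk, tax[[rk]][i]))
    }
    "unclassified"
  }, character(1))
}

#' Filter OTUs by total read count
#'
#' Retains exactly the OTUs whose total count across all samples is strictly
#' greater than `min_reads` ("more than" semantics). The paper's thresholds
#' of record are 100 reads for the all-sample network, 10 for 454 studies
#' and 200 for MiSeq studies. Samples and OTU order are preserved.
#'
#' @param table an [otu_table].
#' @param min_reads positive integer threshold; an OTU is kept iff its total
#'   exceeds this value.
#' @return A filtered [otu_table].
#' @export
filter_by_total_reads <- function(table, min_reads) {
  stopifnot(inherits(table, "otu_table"))
  if (length(min_reads) != 1 || is.na(min_reads) || min_reads < 1) {
    stop("min_reads must be a positive integer (>= 1)")
  }
  totals <- colSums(table$counts)
  keep <- totals > min_reads
  if (sum(keep) < 4) {
    stop(sprintf(
      "fewer than 4 OTUs remain after filtering at min_reads=%d (%d kept); correlation inference needs D >= 4",
      as.integer(min_reads), sum(keep)))
  }
  otu_table(table$counts[, keep, drop = FALSE])
}

#' Group rare genera under higher-level labels
#'
#' Every genus represented by fewer than `min_otus` OTUs (default 15) has
#' its display label replaced by its family when resolved, else its order,
#' reducing label complexity in the clustered network. The number of OTUs is
#' never changed, only labels.
#'
#' @param tax a `taxonomy_map` data frame as returned by [parse_lineages].
#' @param min_otus positive integer; genera with fewer OTUs than this are
#'   relabelled.
#' @return The taxonomy with updated `display_label`.
#' @export
relabel_rare_genera <- function(tax, min_otus = 15) {
  stopifnot(inherits(tax, "data.frame"))
  if (min_otus < 1) stop("min_otus must be >= 1")
  genus_n <- table(tax$genus[!is.na(tax$genus)])
  rare <- names(genus_n)[genus_n < min_otus]
  idx <- which(!is.na(tax$genus) & tax$genus %in% rare)
  for (i in idx) {
    if (!is.na(tax$family[i])) {
      tax$display_label[i] <- paste("family", tax$family[i])
    } else if (!is.na(tax$order[i])) {
      tax$display_label[i] <- paste("order", tax$order[i])
    }
    # genus with neither family nor order resolved keeps its genus label
  }
  tax
}

#' Write an OTU table (with stubs) to tab-separated files
#'
#' Inverse of [read_otu_table]; used by the synthetic-data workflow to
#' materialise communities for downstream steps. Counts round-trip
#' bit-exactly.
#'
#' @param x list with `table`, `taxonomy`, `metadata` (as from
#'   [read_otu_table] or [simulate_community_files]).
#' @param table_path,taxonomy_path,metadata_path output paths.
#' @return Invisibly, the paths written.
#' @export
write_otu_table <- function(x, table_path, taxonomy_path = NULL,
                            metadata_path = NULL) {
  stopifnot(inherits(x$table, "otu_table"))
  df <- data.frame(sample_id = x$table$sample_ids,
                   x$table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(taxonomy_path) && !is.null(x$taxonomy)) {
    tx <- x$taxonomy
    lineage <- vapply(seq_len(nrow(tx)), function(i) {
      paste(na.omit(c(
        if (!is.na(tx$phylum[i])) paste0("p__", tx$phylum[i]),
        if (!is.na(tx$class[i])) paste0("c__", tx$class[i]),
        if (!is.na(tx$order[i])) paste0("o__", tx$order[i]),
        if (!is.na(tx$family[i])) paste0("f__", tx$family[i]),
        if (!is.na(tx$genus[i])) paste0("g__", tx$genus[i]))),
        collapse = ";")
    }, character(1))
    utils::write.table(
      data.frame(otu_id = tx$otu_id, lineage = lineage),
      taxonomy_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(metadata_path) && !is.null(x$metadata)) {
    utils::write.table(x$metadata, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(table_path, taxonomy_path, metadata_path))
}
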