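# The four sample roles every pooled-mapping VCF must provide. Roles are
# assigned explicitly by the caller, never inferred from column order: a
# silent pool swap would invert the direction of every downstream filter.
.POOLSCAN_ROLES <- c("mutant_parent", "wildtype_parent",
                     "mutant_pool", "wildtype_pool")

#' Sample roles of a pooled mapping experiment
#'
#' @return Character vector of the four required roles, in canonical order:
#'   mutant parent, wild-type parent, mutant pool, wild-type pool.
#' @export
sample_roles <- function() .POOLSCAN_ROLES

.check_role_map <- function(sample_role_map) {
  if (is.null(names(sample_role_map)) ||
      !setequal(names(sample_role_map), .POOLSCAN_ROLES)) {
    stop("sample_role_map must name exactly the roles: ",
         paste(.POOLSCAN_ROLES, collapse = ", "))
  }
  sample_role_map[.POOLSCAN_ROLES]
}

#' Read a pooled-sequencing VCF into a variant table
#'
#' Reads a VCF v4.2 with per-sample `AD` (allelic depth) FORMAT values and
#' returns one row per biallelic record. The `AD` field carries read counts in
#' ref,alt order; they become the per-role `<role>_ref` / `<role>_alt` columns
#' of the returned table. Multi-allelic records are skipped with a message by
#' default, or split into one row per alternate allele.
#'
#' @param path VCF file path (plain text or bgzip).
#' @param sample_role_map Named character vector mapping each of the four
#'   roles (see [sample_roles()]) to a VCF sample column name.
#' @param split_multiallelic If `TRUE`, a record with k alternate alleles
#'   yields k rows (ref count shared, per-alt counts from AD); if `FALSE`
#'   (default) such records are skipped and counted in a message.
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`, `class`
#'   (`"SNP"` or `"INDEL"`) and eight count columns `<role>_ref`, `<role>_alt`.
#' @export
read_vcf <- function(path, sample_role_map, split_multiallelic = FALSE) {
  sample_role_map <- .check_role_map(sample_role_map)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  vcf_samples <- colnames(v@gt)[-1]
  missing_samples <- setdiff(unname(sample_role_map), vcf_samples)
  if (length(missing_samples) > 0) {
    stop("VCF is missing sample column(s): ", paste(missing_samples, collapse = ", "))
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(dim(ad))) ad <- matrix(ad, nrow = 1, dimnames = list(NULL, vcf_samples))
  for (role in .POOLSCAN_ROLES) {
    col <- sample_role_map[[role]]
    if (any(is.na(ad[, col]))) {
      stop("missing AD field for sample '", col, "' (role ", role, ")")
    }
  }

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  multi <- grepl(",", alt, fixed = TRUE)
  rows <- list()
  emit <- function(i, alt_allele, alt_slot) {
    counts <- lapply(.POOLSCAN_ROLES, function(role) {
      parts <- as.numeric(strsplit(ad[i, sample_role_map[[role]]], ",", fixed = TRUE)[[1]])
      c(parts[1], parts[alt_slot + 1L])
    })
    names(counts) <- .POOLSCAN_ROLES
    rec <- data.frame(chrom = chrom[i], pos = pos[i], ref = ref[i],
                      alt = alt_allele,
                      class = if (nchar(ref[i]) == 1L && nchar(alt_allele) == 1L) "SNP" else "INDEL",
                      stringsAsFactors = FALSE)
    for (role in .POOLSCAN_ROLES) {
      rec[[paste0(role, "_ref")]] <- counts[[role]][1]
      rec[[paste0(role, "_alt")]] <- counts[[role]][2]
    }
    rec
  }
  n_skipped <- 0L
  for (i in seq_along(pos)) {
    if (!multi[i]) {
      if (!grepl("^[ACGT]+$", ref[i]) || !grepl("^[ACGT]+$", alt[i]) || ref[i] == alt[i]) next
      rows[[length(rows) + 1L]] <- emit(i, alt[i], 1L)
    } else if (split_multiallelic) {
      alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
      for (j in seq_along(alts)) {
        if (!grepl("^[ACGT]+$", alts[j])) next
        rows[[length(rows) + 1L]] <- emit(i, alts[j], j)
      }
    } else {
      n_skipped <- n_skipped + 1L
    }
  }
  if (n_skipped > 0L) {
    message("read_vcf: skipped ", n_skipped, " multi-allelic record(s); ",
            "use split_multiallelic = TRUE to keep them")
  }
  if (length(rows) == 0L) return(.empty_variant_table())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.empty_variant_table <- function() {
  out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), class = character(),
                    stringsAsFactors = FALSE)
  for (role in .POOLSCAN_ROLES) {
    out[[paste0(role, "_ref")]] <- numeric()
    out[[paste0(role, "_alt")]] <- numeric()
  }
  out
}

#' Write a variant table as a minimal VCF v4.2
#'
#' Emits a deterministic, byte-stable VCF (no timestamps) with a single `AD`
#' FORMAT field, so that `read_vcf()` followed by `write_vcf()` is a fixed
#' point on files produced here.
#'
#' @param variants Variant table as returned by [read_vcf()] or the simulator.
#' @param path Output path.
#' @param sample_role_map Named character vector mapping roles to the sample
#'   column names to write; defaults to the role names themselves.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path,
                      sample_role_map = stats::setNames(.POOLSCAN_ROLES, .POOLSCAN_ROLES)) {
  sample_role_map <- .check_role_map(sample_role_map)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=poolscan",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allelic depths for the ref and alt alleles in the order listed\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", unname(sample_role_map)), collapse = "\t")
  )
  body <- character(nrow(variants))
  if (nrow(variants) > 0) {
    sample_fields <- sapply(.POOLSCAN_ROLES, function(role) {
      paste0(format(variants[[paste0(role, "_ref")]], scientific = FALSE, trim = TRUE),
             ",",
             format(variants[[paste0(role, "_alt")]], scientific = FALSE, trim = TRUE))
    })
    if (is.null(dim(sample_fields))) {
      sample_fields <- matrix(sample_fields, nrow = 1)
    }
    body <- paste(variants$chrom,
                  format(variants$pos, scientific = FALSE, trim = TRUE),
                  ".", variants$ref, variants$alt, ".", "PASS", ".", "AD",
                  apply(sample_fields, 1, paste, collapse = "\t"),
                  sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}
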