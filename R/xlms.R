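# Post-identification crosslinking-MS pipeline: link classification,
# qualitative score/consistency filters, domain mapping, targeted
# quantification, differential analysis and condition-specific selection.

proteinLengthDefault <- 440L

#' Classify a crosslinked peptide by its residue positions
#'
#' Four link categories: a \emph{crosslink} joins two different residues; a
#' \emph{monolink} is a single reagent-modified residue (no second
#' position); a \emph{selflink} joins two positionally identical residues
#' and is therefore necessarily inter-molecular; a \emph{zerolink} is a
#' direct covalent bond without linker, flagged by upstream identification
#' (hydrazide chemistry only) and carried through unchanged.
#'
#' @param posA,posB 1-based residue positions; \code{posB} may be \code{NA}
#'   (monolink). Vectorised.
#' @param reagent crosslinker, \code{"DSS"} or \code{"PDH"}.
#' @param zerolink logical, upstream zerolink flag.
#' @param proteinLength sequence length for validation; default 440.
#' @return Character vector of link types.
#' @examples
#' classifyLink(207, 207)      # selflink
#' classifyLink(79, 338)       # crosslink
#' classifyLink(150, NA)       # monolink
#' @export
classifyLink <- function(posA, posB = NA, reagent = "DSS", zerolink = FALSE,
                         proteinLength = proteinLengthDefault) {
    n <- max(length(posA), length(posB))
    posA <- rep_len(posA, n); posB <- rep_len(posB, n)
    zerolink <- rep_len(zerolink, n)
    bad <- posA < 1 | posA > proteinLength |
        (!is.na(posB) & (posB < 1 | posB > proteinLength))
    if (any(bad))
        stop(sprintf("residue positions outside 1..%d", proteinLength),
             call. = FALSE)
    ifelse(zerolink, "zerolink",
        ifelse(is.na(posB), "monolink",
            ifelse(posA == posB, "selflink", "crosslink")))
}

# Order-normalised unique-peptide key: position pair + type + reagent
peptideKey <- function(posA, posB, linkType, reagent) {
    lo <- pmin(posA, posB, na.rm = TRUE)
    hi <- pmax(posA, posB, na.rm = TRUE)
    pos <- ifelse(is.na(posB), as.character(posA),
                  paste0(lo, "-", hi))
    paste(pos, linkType, reagent, sep = "|")
}

withKey <- function(records) {
    if (is.null(records$linkType))
        records$linkType <- classifyLink(records$posA, records$posB,
                                         records$reagent)
    records$key <- peptideKey(records$posA, records$posB, records$linkType,
                              records$reagent)
    records
}

#' Domain boundaries of the Bik1 sequence
#'
#' Named intervals on the 440-residue sequence: the CAP-Gly domain
#' (1-80), the flexible linker L1 (81-188), the central coiled coil
#' (189-389) and the C-terminal region (390-440). Sub-intervals (linker
#' L2, zinc finger, tail and the three coiled-coil segments) are returned
#' at \code{level = "sub"}; only top-level regions tile the sequence
#' without overlap and are used for mapping.
#'
#' @return A data.frame with \code{region}, \code{start}, \code{end},
#'   \code{level}.
#' @export
bik1Domains <- function() {
    data.frame(
        region = c("CAP-Gly", "L1", "coiled coil", "C-terminal",
                   "L2", "zinc finger", "tail", "cc-A", "cc-B", "cc-C"),
        start = c(1, 81, 189, 390, 390, 420, 432, 189, 302, 363),
        end = c(80, 188, 389, 440, 419, 431, 440, 297, 357, 389),
        level = c(rep("top", 4), rep("sub", 6)))
}

mapRegion <- function(pos, map) {
    top <- map[map$level == "top", ]
    out <- rep(NA_character_, length(pos))
    for (i in seq_len(nrow(top)))
        out[pos >= top$start[i] & pos <= top$end[i]] <- top$region[i]
    out
}

#' Map crosslink records to sequence regions
#'
#' Each position is assigned its top-level region; the pair label is
#' order-normalised (alphabetical), so (CAP-Gly, coiled coil) and
#' (coiled coil, CAP-Gly) aggregate together. Monolinks get a single
#' region.
#'
#' @param records a crosslink record data.frame with \code{posA},
#'   \code{posB}.
#' @param map a domain map from [bik1Domains()].
#' @return The records with added \code{regionA}, \code{regionB} and
#'   \code{regionPair} columns.
#' @export
assignDomains <- function(records, map = bik1Domains()) {
    records$regionA <- mapRegion(records$posA, map)
    records$regionB <- ifelse(is.na(records$posB), NA_character_,
                              mapRegion(records$posB, map))
    a <- records$regionA; b <- records$regionB
    records$regionPair <- ifelse(is.na(b), a,
        paste(pmin(a, b), pmax(a, b), sep = " / "))
    records
}

#' Spectral counts per region pair and link category
#'
#' Sums \code{spectraCount} over order-normalised region pairs within each
#' link category, the summary used to ask which parts of the protein are
#' most interconnected.
#'
#' @inheritParams assignDomains
#' @return A data.frame with \code{regionPair}, \code{linkType} and
#'   \code{spectra}.
#' @export
domainPairCounts <- function(records, map = bik1Domains()) {
    records <- assignDomains(withKey(records), map)
    agg <- stats::aggregate(spectraCount ~ regionPair + linkType,
                            data = records, FUN = sum)
    names(agg)[3] <- "spectra"
    agg[order(agg$linkType, -agg$spectra), , drop = FALSE]
}

#' Qualitative filter for amine-reactive (DSS) crosslink identifications
#'
#' Conservative two-part rule: every retained observation must exceed the
#' score threshold (strictly, ld.Score > 20), and a unique peptide is kept
#' within a condition only when such observations occur in at least two
#' distinct replicates. The stricter reading — the score cut applies to
#' each contributing replicate, not just one — is used.
#'
#' @param records identification data.frame (columns \code{posA},
#'   \code{posB}, \code{ldScore}, \code{condition}, \code{replicate},
#'   \code{reagent}, optionally \code{linkType}).
#' @param minScore score threshold, strict; default 20.
#' @param minReplicates distinct-replicate requirement; default 2.
#' @return The surviving records (same columns, plus \code{key} and
#'   \code{linkType}).
#' @export
filterQualitativeDSS <- function(records, minScore = 20, minReplicates = 2) {
    records <- withKey(records)
    records <- records[records$ldScore > minScore, , drop = FALSE]
    if (nrow(records) == 0L) return(records)
    grp <- paste(records$condition, records$key, sep = "\r")
    nrep <- vapply(split(records$replicate, grp),
                   function(r) length(unique(r)), integer(1))
    keep <- grp %in% names(nrep)[nrep >= minReplicates]
    records[keep, , drop = FALSE]
}

#' Qualitative filter for acid-reactive (PDH) crosslink identifications
#'
#' Conjunction of three strict thresholds — ld.Score > 25, deltaS > 0.9
#' and FDR < 0.05 — with no replicate requirement (these experiments were
#' run as single replicates). Records missing deltaS or FDR are rejected
#' with a warning.
#'
#' @param records identification data.frame (as in
#'   [filterQualitativeDSS()], plus \code{deltaS} and \code{fdr}).
#' @param minScore,minDeltaS,maxFdr the three thresholds.
#' @return The surviving records.
#' @export
filterQualitativePDH <- function(records, minScore = 25, minDeltaS = 0.9,
                                 maxFdr = 0.05) {
    records <- withKey(records)
    if (nrow(records) == 0L) return(records)
    missing_ <- is.na(records$deltaS) | is.na(records$fdr)
    if (any(missing_))
        warning(sprintf("%d record(s) missing deltaS or FDR rejected",
                        sum(missing_)))
    keep <- !missing_ & records$ldScore > minScore &
        records$deltaS > minDeltaS & records$fdr < maxFdr
    records[keep, , drop = FALSE]
}

#' Normalised abundances from targeted transition areas
#'
#' The abundance of a crosslinked peptide is the sum of the integrated
#' areas of its ten common transitions (five for the heavy and five for
#' the light form) divided by the householder (non-crosslinked reference)
#' peptide area in the same replicate, correcting for protein-level
#' variation between runs.
#'
#' @param transitions transition table (columns \code{peptideId},
#'   \code{condition}, \code{replicate}, \code{form}, \code{transition},
#'   \code{area}).
#' @param householder householder peptide identifier; default the tryptic
#'   reference peptide \code{"MVLEEVQPTFDR"}.
#' @return A data.frame with \code{peptideId}, \code{condition},
#'   \code{replicate}, \code{abundance}.
#' @export
normalizeQuant <- function(transitions, householder = "MVLEEVQPTFDR") {
    hh <- transitions[transitions$peptideId == householder, , drop = FALSE]
    xl <- transitions[transitions$peptideId != householder, , drop = FALSE]
    if (nrow(xl) == 0L)
        return(data.frame(peptideId = character(0), condition = character(0),
                          replicate = integer(0), abundance = numeric(0)))
    combos <- unique(xl[, c("peptideId", "condition", "replicate")])
    out <- lapply(seq_len(nrow(combos)), function(i) {
        sel <- xl$peptideId == combos$peptideId[i] &
            xl$condition == combos$condition[i] &
            xl$replicate == combos$replicate[i]
        sub <- xl[sel, , drop = FALSE]
        for (form in c("heavy", "light"))
            if (sum(sub$form == form) < 5L)
                stop(sprintf(
                    "peptide %s (%s, replicate %d): fewer than 5 %s transitions",
                    combos$peptideId[i], combos$condition[i],
                    combos$replicate[i], form), call. = FALSE)
        hsel <- hh$condition == combos$condition[i] &
            hh$replicate == combos$replicate[i]
        if (!any(hsel))
            stop(sprintf(
                "householder peptide missing in condition %s, replicate %d",
                combos$condition[i], combos$replicate[i]), call. = FALSE)
        data.frame(peptideId = combos$peptideId[i],
                   condition = combos$condition[i],
                   replicate = combos$replicate[i],
                   abundance = sum(sub$area) / sum(hh$area[hsel]))
    })
    do.call(rbind, out)
}

#' Differential abundance between two conditions
#'
#' Per peptide: \eqn{\log_2} fold change of the condition means and a
#' two-sided unpaired Student's t-test (pooled variance by default; set
#' \code{varEqual = FALSE} for Welch). Peptides are flagged as enriched
#' when \eqn{\log_2 FC > 1} (strictly). Peptides with non-positive means
#' are skipped with a warning; a peptide absent in a replicate simply does
#' not contribute to that condition's mean.
#'
#' @param abundances output of [normalizeQuant()].
#' @param conditionA,conditionB the two condition labels (fold change is
#'   A over B).
#' @param varEqual pooled-variance Student's t (default) or Welch.
#' @param fcThreshold enrichment threshold on \eqn{\log_2 FC}; default 1.
#' @param pAdjust \code{"none"} (default; raw significance is reported) or
#'   \code{"BH"} for Benjamini-Hochberg adjusted p-values in an extra
#'   \code{pAdjusted} column.
#' @return A data.frame with \code{peptideId}, \code{log2FC},
#'   \code{pValue}, \code{enriched} (and \code{pAdjusted} when requested).
#' @export
differentialAnalysis <- function(abundances, conditionA, conditionB,
                                 varEqual = TRUE, fcThreshold = 1,
                                 pAdjust = c("none", "BH")) {
    pAdjust <- match.arg(pAdjust)
    peps <- unique(abundances$peptideId)
    out <- lapply(peps, function(p) {
        a <- abundances$abundance[abundances$peptideId == p &
                                  abundances$condition == conditionA]
        b <- abundances$abundance[abundances$peptideId == p &
                                  abundances$condition == conditionB]
        if (length(a) < 2L || length(b) < 2L) return(NULL)
        ma <- mean(a); mb <- mean(b)
        if (ma <= 0 || mb <= 0) {
            warning(sprintf("peptide %s skipped: non-positive mean", p))
            return(NULL)
        }
        p_ <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
            if (ma == mb) 1 else 0     # degenerate constant groups
        } else {
            stats::t.test(a, b, var.equal = varEqual)$p.value
        }
        data.frame(peptideId = p, log2FC = log2(ma / mb), pValue = p_,
                   enriched = log2(ma / mb) > fcThreshold)
    })
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out) == 0L)
        return(data.frame(peptideId = character(0), log2FC = numeric(0),
                          pValue = numeric(0), enriched = logical(0)))
    out <- do.call(rbind, out)
    if (pAdjust == "BH")
        out$pAdjusted <- stats::p.adjust(out$pValue, method = "BH")
    out
}

#' Condition-specific (conformo-specific) crosslinked peptides
#'
#' Peptides present in exactly one condition's filtered set; such links
#' report on a conformational state unique to that condition and are the
#' candidates for targeted quantification.
#'
#' @param filtered filtered identification records (output of a
#'   qualitative filter) across conditions.
#' @return A data.frame with \code{key}, \code{posA}, \code{posB},
#'   \code{linkType}, \code{reagent} and the single \code{condition} the
#'   peptide is specific to.
#' @export
conformoSpecific <- function(filtered) {
    filtered <- withKey(filtered)
    if (nrow(filtered) == 0L)
        return(data.frame(key = character(0), posA = integer(0),
                          posB = integer(0), linkType = character(0),
                          reagent = character(0), condition = character(0)))
    sets <- unique(filtered[, c("key", "condition")])
    cnt <- table(sets$key)
    uniq <- names(cnt)[cnt == 1L]
    sel <- sets[sets$key %in% uniq, , drop = FALSE]
    info <- filtered[!duplicated(filtered$key),
                     c("key", "posA", "posB", "linkType", "reagent")]
    out <- merge(sel, info, by = "key")
    out[order(out$condition, out$key),
        c("key", "posA", "posB", "linkType", "reagent", "condition")]
}

#' Unique-peptide counts per link category
#'
#' Counts unique crosslinked peptides (at position-pair resolution) per
#' category for one condition or across all records; the total is the sum
#' of the categories by construction.
#'
#' @param records (filtered) identification records.
#' @param condition optional condition label to restrict to.
#' @return A list with \code{crosslinks}, \code{monolinks},
#'   \code{selflinks}, \code{zerolinks} and \code{total}.
#' @export
summarizeCounts <- function(records, condition = NULL) {
    records <- withKey(records)
    if (!is.null(condition))
        records <- records[records$condition == condition, , drop = FALSE]
    uniq <- records[!duplicated(records$key), , drop = FALSE]
    n <- function(ty) sum(uniq$linkType == ty)
    out <- list(crosslinks = n("crosslink"), monolinks = n("monolink"),
                selflinks = n("selflink"), zerolinks = n("zerolink"))
    out$total <- sum(unlist(out))
    out
}
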