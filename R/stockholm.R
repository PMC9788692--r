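# Stockholm 1.0 reading/writing and structure-string parsing.
#
# Dialect: per-sequence metadata is carried as
#   #=GS <id> GENE   <domain>      -> metadata$gene_domain
#   #=GS <id> PHYLUM <name>        -> metadata$phylum
#   #=GS <id> ENV    <gut|non_gut|unknown> -> metadata$environment
# Unknown #=GS tags are preserved verbatim as extra metadata columns.

GAP_INPUT_CHARS <- c(".", "_", "~", "-")

.normalizeSeq <- function(s) {
    s <- toupper(s)
    s <- gsub("T", "U", s, fixed = TRUE)
    gsub("[._~]", GAP_CHAR, s)
}

#' Construct a MotifAlignment
#'
#' @param rows named character vector of gapped sequences (names are the
#'   sequence ids). \code{T} is normalized to \code{U}; the gap characters
#'   \code{. _ ~} are normalized to \code{-}.
#' @param ssCons consensus structure string of the same width.
#' @param metadata optional data.frame or DataFrame keyed by sequence id
#'   (rownames, or matched in order when unnamed).
#' @param name alignment name.
#' @return a \linkS4class{MotifAlignment}.
#' @examples
#' aln <- MotifAlignment(c(s1 = "GGCAACC", s2 = "GGAAACC"), "<<...>>")
#' ncol(aln)
#' @export
MotifAlignment <- function(rows, ssCons, metadata = NULL, name = "alignment") {
    rows <- vapply(rows, .normalizeSeq, character(1))
    ids <- names(rows)
    resid <- gsub("-", "", rows, fixed = TRUE)
    bad <- grepl("[^ACGU]", resid)
    if (any(bad))
        warning("non-ACGU residue codes in ",
            paste(utils::head(ids[bad], 5L), collapse = ", "),
            "; they are treated as gaps in profile computations")
    md <- .asMetadata(metadata, ids)
    new("MotifAlignment", name = name, rows = rows,
        ssCons = ssCons, metadata = md)
}

.asMetadata <- function(metadata, ids) {
    if (is.null(metadata))
        return(S4Vectors::DataFrame(row.names = ids))
    md <- S4Vectors::DataFrame(metadata)
    if (is.null(rownames(md))) {
        if (nrow(md) != length(ids))
            stop("metadata rows do not match the sequences")
        rownames(md) <- ids
    } else {
        missing <- setdiff(rownames(md), ids)
        if (length(missing))
            stop("metadata for unknown sequence ids: ",
                paste(utils::head(missing, 5L), collapse = ", "))
        md <- md[match(ids, rownames(md)), , drop = FALSE]
        rownames(md) <- ids
    }
    if ("environment" %in% colnames(md)) {
        env <- as.character(md$environment)
        env[is.na(env)] <- "unknown"
        bad <- !env %in% c("gut", "non_gut", "unknown")
        if (any(bad)) {
            warning("unrecognised environment labels set to 'unknown': ",
                paste(unique(env[bad]), collapse = ", "))
            env[bad] <- "unknown"
        }
        md$environment <- env
    }
    md
}

#' Read a single-alignment Stockholm 1.0 file
#'
#' Parses sequences (interleaved blocks are concatenated), the
#' \code{#=GC SS_cons} consensus structure and all \code{#=GS} per-sequence
#' tags. The tags \code{GENE}, \code{PHYLUM} and \code{ENV} are mapped to
#' the metadata columns \code{gene_domain}, \code{phylum} and
#' \code{environment}; other tags are kept verbatim under their own name.
#'
#' @param path path to a Stockholm file.
#' @param name alignment name (default: file name without extension).
#' @return a \linkS4class{MotifAlignment}.
#' @seealso [writeStockholm()], [parseSSCons()]
#' @examples
#' sto <- system.file("extdata", "example_motif.sto",
#'     package = "MotifContrast")
#' aln <- readStockholm(sto)
#' alnMetadata(aln)
#' @export
readStockholm <- function(path, name = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(name))
        name <- tools::file_path_sans_ext(basename(path))
    lines <- readLines(path, warn = FALSE)
    if (!length(lines) || !grepl("^# STOCKHOLM", lines[[1]]))
        stop("not a Stockholm 1.0 file (missing '# STOCKHOLM' header): ",
            path)
    seqs <- list()
    gs <- list()
    ss <- character(0)
    for (ln in lines[-1]) {
        if (grepl("^\\s*$", ln)) next
        if (grepl("^//", ln)) break
        if (grepl("^#=GS\\s", ln)) {
            f <- strsplit(trimws(ln), "\\s+")[[1]]
            if (length(f) < 4L) stop("malformed #=GS line: ", ln)
            gs[[length(gs) + 1L]] <- list(id = f[2], tag = f[3],
                value = paste(f[-(1:3)], collapse = " "))
        } else if (grepl("^#=GC\\s+SS_cons\\s", ln)) {
            f <- strsplit(trimws(ln), "\\s+")[[1]]
            ss <- c(ss, f[3])
        } else if (grepl("^#", ln)) {
            next  # other annotation lines ignored
        } else {
            f <- strsplit(trimws(ln), "\\s+")[[1]]
            if (length(f) != 2L) stop("malformed sequence line: ", ln)
            id <- f[1]
            seqs[[id]] <- paste0(if (is.null(seqs[[id]])) "" else seqs[[id]],
                f[2])
        }
    }
    if (!length(ss))
        stop("missing #=GC SS_cons line in ", path)
    ss <- paste(ss, collapse = "")
    if (!length(seqs)) stop("no sequences in ", path)
    rows <- unlist(seqs)
    ragged <- nchar(rows) != nchar(ss)
    if (any(ragged))
        stop("sequence length differs from SS_cons for: ",
            paste(utils::head(names(rows)[ragged], 5L), collapse = ", "))
    md <- NULL
    if (length(gs)) {
        tagmap <- c(GENE = "gene_domain", PHYLUM = "phylum",
            ENV = "environment")
        tags <- vapply(gs, `[[`, "", "tag")
        cols <- ifelse(tags %in% names(tagmap), tagmap[tags], tags)
        md <- data.frame(row.names = names(rows))
        for (k in seq_along(gs)) {
            col <- cols[[k]]
            id <- gs[[k]]$id
            if (!id %in% names(rows))
                stop("#=GS line for unknown sequence id: ", id)
            if (!col %in% colnames(md)) md[[col]] <- NA_character_
            md[id, col] <- gs[[k]]$value
        }
    }
    MotifAlignment(rows, ss, metadata = md, name = name)
}

#' Write a MotifAlignment as Stockholm 1.0
#'
#' Emits a canonical single-block file with \code{#=GS} metadata lines and
#' the \code{#=GC SS_cons} annotation; reading it back yields an equal
#' alignment.
#'
#' @param aln a \linkS4class{MotifAlignment}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeStockholm <- function(aln, path) {
    stopifnot(is(aln, "MotifAlignment"))
    ids <- seqIDs(aln)
    out <- c("# STOCKHOLM 1.0", "")
    md <- alnMetadata(aln)
    tagmap <- c(gene_domain = "GENE", phylum = "PHYLUM",
        environment = "ENV")
    if (nrow(md)) {
        for (col in colnames(md)) {
            tag <- if (col %in% names(tagmap)) tagmap[[col]] else col
            v <- as.character(md[[col]])
            keep <- !is.na(v)
            out <- c(out, sprintf("#=GS %s %s %s", ids[keep], tag, v[keep]))
        }
        if (ncol(md)) out <- c(out, "")
    }
    w <- max(nchar(ids), nchar("#=GC SS_cons"))
    out <- c(out,
        sprintf("%-*s %s", w, ids, gappedSeqs(aln)),
        sprintf("%-*s %s", w, "#=GC SS_cons", ssCons(aln)),
        "//")
    writeLines(out, path)
    invisible(path)
}

#' Parse a consensus structure string into a pair table
#'
#' Bracket characters \code{<> () [] \{\}} denote nested base pairs (each
#' bracket type is matched with its own stack); matched upper/lower-case
#' letter pairs (\code{Aa}, \code{Bb}, ...) denote pseudoknot layers.
#' The characters \code{. , _ - : ~} mark unpaired columns.
#'
#' @param ss structure string.
#' @return data.frame with 1-based columns \code{i}, \code{j} (i < j) and
#'   \code{layer} (\code{"nested"} or \code{"pseudoknot"}), ordered by
#'   \code{i}. Each column occurs in at most one pair.
#' @examples
#' parseSSCons("<<..AA..>>..aa")
#' @export
parseSSCons <- function(ss) {
    stopifnot(is.character(ss), length(ss) == 1L)
    chars <- strsplit(ss, "")[[1]]
    openers <- c("<" = ">", "(" = ")", "[" = "]", "{" = "}")
    stacks <- new.env(parent = emptyenv())
    pairs_i <- integer(0); pairs_j <- integer(0); layer <- character(0)
    push <- function(key, pos) assign(key,
        c(if (exists(key, stacks)) get(key, stacks) else integer(0), pos),
        stacks)
    pop <- function(key, sym, pos) {
        st <- if (exists(key, stacks)) get(key, stacks) else integer(0)
        if (!length(st))
            stop("unbalanced structure: unmatched '", sym,
                "' at column ", pos)
        assign(key, st[-length(st)], stacks)
        st[length(st)]
    }
    for (pos in seq_along(chars)) {
        ch <- chars[[pos]]
        if (ch %in% c(".", ",", "_", "-", ":", "~")) next
        if (ch %in% names(openers)) {
            push(paste0("b", ch), pos)
        } else if (ch %in% openers) {
            op <- names(openers)[match(ch, openers)]
            i <- pop(paste0("b", op), ch, pos)
            pairs_i <- c(pairs_i, i); pairs_j <- c(pairs_j, pos)
            layer <- c(layer, "nested")
        } else if (grepl("^[A-Z]$", ch)) {
            push(paste0("p", ch), pos)
        } else if (grepl("^[a-z]$", ch)) {
            i <- pop(paste0("p", toupper(ch)), ch, pos)
            pairs_i <- c(pairs_i, i); pairs_j <- c(pairs_j, pos)
            layer <- c(layer, "pseudoknot")
        } else {
            stop("unsupported structure character '", ch, "' at column ",
                pos)
        }
    }
    for (key in ls(stacks)) {
        st <- get(key, stacks)
        if (length(st)) {
            sym <- substr(key, 2L, 2L)
            stop("unbalanced structure: unmatched '", sym, "' at column ",
                st[length(st)])
        }
    }
    ord <- order(pairs_i)
    data.frame(i = pairs_i[ord], j = pairs_j[ord],
        layer = layer[ord], stringsAsFactors = FALSE)
}

#' Remove duplicate sequences from an alignment
#'
#' Keeps the first occurrence of each distinct ungapped sequence string;
#' the column set is unchanged. The number of removed rows is attached as
#' attribute \code{"nRemoved"} and reported via \code{message()}.
#'
#' @param aln a \linkS4class{MotifAlignment}.
#' @return the deduplicated \linkS4class{MotifAlignment}.
#' @export
deduplicate <- function(aln) {
    stopifnot(is(aln, "MotifAlignment"))
    ungapped <- gsub("-", "", gappedSeqs(aln), fixed = TRUE)
    keep <- !duplicated(ungapped)
    out <- aln[which(keep)]
    nRemoved <- sum(!keep)
    message(nRemoved, " duplicate sequence(s) removed; ",
        nrow(out), " unique sequence(s) kept")
    attr(out, "nRemoved") <- nRemoved
    out
}

#' Remove sequences that overlap another motif's predictions
#'
#' Drops rows whose sequence id appears in \code{otherIDs} (for example,
#' ids already assigned to a homologous motif). The number of removed rows
#' is attached as attribute \code{"nRemoved"}.
#'
#' @param aln a \linkS4class{MotifAlignment}.
#' @param otherIDs character vector of sequence ids to remove.
#' @return the filtered \linkS4class{MotifAlignment}.
#' @export
removeOverlap <- function(aln, otherIDs) {
    stopifnot(is(aln, "MotifAlignment"))
    keep <- !seqIDs(aln) %in% otherIDs
    out <- aln[which(keep)]
    nRemoved <- sum(!keep)
    message(nRemoved, " overlapping sequence(s) removed; ",
        nrow(out), " kept")
    attr(out, "nRemoved") <- nRemoved
    out
}

#' Export ungapped sequences as FASTA
#'
#' @param aln a \linkS4class{MotifAlignment}.
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @importFrom Biostrings RNAStringSet writeXStringSet
#' @export
writeFastaUngapped <- function(aln, path) {
    stopifnot(is(aln, "MotifAlignment"))
    ungapped <- gsub("-", "", gappedSeqs(aln), fixed = TRUE)
    xs <- Biostrings::RNAStringSet(ungapped)
    Biostrings::writeXStringSet(xs, path)
    invisible(path)
}

#' Read ungapped RNA sequences from FASTA
#'
#' DNA alphabets are accepted and normalized to RNA (T to U).
#'
#' @param path FASTA file.
#' @return named character vector of ungapped RNA sequences.
#' @importFrom Biostrings readBStringSet
#' @export
readFastaRNA <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    xs <- Biostrings::readBStringSet(path)
    seqs <- .normalizeSeq(as.character(xs))
    seqs <- gsub("-", "", seqs, fixed = TRUE)
    names(seqs) <- sub("\\s.*$", "", names(xs))
    seqs
}
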