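#' Construct a validated, topologically sorted pedigree
#'
#' Builds a pedigree object from raw animal/sire/dam records. Records are
#' deduplicated, parents that are referenced but not listed as animals are
#' added as founders, and animals are re-ordered so that every known parent
#' precedes its offspring. Internally animals are recoded to dense 1-based
#' integer indices in that topological order; the original identifiers are
#' kept as tokens.
#'
#' @param animal character vector of animal identifiers (non-empty tokens).
#' @param sire,dam character vectors of parent identifiers; `NA`, `""` or
#'   `"0"` denote an unknown parent.
#' @param sex optional character vector, `"M"`, `"F"` or unknown (`NA`,
#'   `""`, `"0"`, `"U"`).
#' @return An object of class `"pedigree"`: a list with elements
#'   `id` (token), `sire`/`dam` (integer index into `id`, `NA` if unknown),
#'   `sex` (character, `"M"`, `"F"` or `"U"`), `generation` (0 for founders,
#'   else 1 + max parental generation), `n`, and `n_added_founders`, the
#'   number of parents that had to be promoted to founders.
#' @examples
#' ped <- pedigree(c("o", "s", "d"), c("s", "0", "0"), c("d", "0", "0"))
#' ped$id          # sorted: parents before offspring
#' @export
pedigree <- function(animal, sire, dam, sex = NULL) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  if (length(sire) != length(animal) || length(dam) != length(animal))
    stop("animal, sire and dam must have equal length")
  unk <- function(x) is.na(x) | x == "" | x == "0"
  if (any(unk(animal))) stop("animal ids must be non-empty tokens")
  sire[unk(sire)] <- NA_character_
  dam[unk(dam)] <- NA_character_
  if (is.null(sex)) {
    sex <- rep(NA_character_, length(animal))
  } else {
    sex <- toupper(as.character(sex))
    sex[!sex %in% c("M", "F")] <- NA_character_
  }
  if (length(sex) != length(animal)) stop("sex must match animal length")

  # deduplicate; identical repeated records are fine, conflicts are not
  if (anyDuplicated(animal)) {
    key <- paste(animal, sire, dam, sep = "\r")
    keep <- !duplicated(key)
    animal <- animal[keep]; sire <- sire[keep]; dam <- dam[keep]
    sex <- sex[keep]
    if (anyDuplicated(animal)) {
      bad <- animal[duplicated(animal)][1L]
      stop("duplicate animal '", bad, "' listed with conflicting parents")
    }
  }

  # promote unlisted parents to founders
  parents <- unique(c(sire[!is.na(sire)], dam[!is.na(dam)]))
  missing <- setdiff(parents, animal)
  n_added <- length(missing)
  if (n_added > 0L) {
    warning(n_added, " parent(s) not listed as animals; added as founders")
    in_sire <- missing %in% sire
    animal <- c(animal, missing)
    sire <- c(sire, rep(NA_character_, n_added))
    dam <- c(dam, rep(NA_character_, n_added))
    sex <- c(sex, ifelse(in_sire, "M", "F"))
  }

  n <- length(animal)
  si <- match(sire, animal)
  di <- match(dam, animal)
  if (any(!is.na(si) & si == seq_len(n)) || any(!is.na(di) & di == seq_len(n)))
    stop("animal '", animal[which(si == seq_len(n) | di == seq_len(n))[1L]],
         "' is its own parent")

  # Kahn topological sort over the parent -> offspring DAG
  indeg <- (!is.na(si)) + (!is.na(di))
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(si[i])) kids[[si[i]]] <- c(kids[[si[i]]], i)
    if (!is.na(di[i])) kids[[di[i]]] <- c(kids[[di[i]]], i)
  }
  # order_out doubles as the work queue: head chases tail
  order_out <- integer(n)
  gen <- integer(n)
  roots <- which(indeg == 0L)
  k <- length(roots)
  order_out[seq_len(k)] <- roots
  head <- 0L
  while (head < k) {
    head <- head + 1L
    i <- order_out[head]
    for (j in kids[[i]]) {
      gen[j] <- max(gen[j], gen[i] + 1L)
      indeg[j] <- indeg[j] - 1L
      if (indeg[j] == 0L) {
        k <- k + 1L
        order_out[k] <- j
      }
    }
  }
  if (k < n) {
    on_cycle <- setdiff(seq_len(n), order_out[seq_len(k)])
    stop("pedigree contains a cycle involving animal '",
         animal[on_cycle[1L]], "'")
  }

  perm <- order_out
  rank <- integer(n); rank[perm] <- seq_len(n)
  structure(
    list(
      id = animal[perm],
      sire = ifelse(is.na(si[perm]), NA_integer_, rank[si[perm]]),
      dam = ifelse(is.na(di[perm]), NA_integer_, rank[di[perm]]),
      sex = ifelse(is.na(sex[perm]), "U", sex[perm]),
      generation = gen[perm],
      n = n,
      n_added_founders = n_added
    ),
    class = "pedigree"
  )
}

#' Load a pedigree from a delimited text file
#'
#' Reads a header-bearing comma- or tab-delimited file with columns
#' `animal,sire,dam` and optionally `sex`; `"0"` or an empty field denotes an
#' unknown parent. The delimiter is detected from the header line.
#'
#' @param file path to the pedigree file.
#' @return A [pedigree()] object.
#' @export
read_pedigree <- function(file) {
  header <- readLines(file, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  d <- utils::read.table(file, header = TRUE, sep = sep,
                         colClasses = "character", strip.white = TRUE)
  names(d) <- tolower(names(d))
  req <- c("animal", "sire", "dam")
  if (!all(req %in% names(d)))
    stop("pedigree file must have columns animal, sire, dam")
  pedigree(d$animal, d$sire, d$dam,
           sex = if ("sex" %in% names(d)) d$sex else NULL)
}

#' Write a pedigree to a delimited text file
#'
#' Inverse of [read_pedigree()]; the round trip is lossless up to the
#' topological ordering imposed by [pedigree()].
#'
#' @param ped a [pedigree()] object.
#' @param file output path.
#' @param sep field delimiter, `","` or `"\t"`.
#' @export
write_pedigree <- function(ped, file, sep = ",") {
  stopifnot(inherits(ped, "pedigree"))
  d <- as.data.frame(ped)
  d$sire[is.na(d$sire)] <- "0"
  d$dam[is.na(d$dam)] <- "0"
  utils::write.table(d[c("animal", "sire", "dam", "sex")], file, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @method as.data.frame pedigree
#' @export
as.data.frame.pedigree <- function(x, ...) {
  data.frame(
    animal = x$id,
    sire = ifelse(is.na(x$sire), NA_character_, x$id[x$sire]),
    dam = ifelse(is.na(x$dam), NA_character_, x$id[x$dam]),
    sex = x$sex,
    generation = x$generation,
    stringsAsFactors = FALSE
  )
}

#' @method print pedigree
#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", x$n, "animals,",
      sum(is.na(x$sire) & is.na(x$dam)), "founders,",
      max(x$generation), "generations\n")
  if (x$n_added_founders > 0L)
    cat("  (", x$n_added_founders, "unlisted parents added as founders )\n")
  invisible(x)
}

#' @method summary pedigree
#' @export
summary.pedigree <- function(object, ...) {
  fac <- inbreeding(object)
  out <- list(
    n = object$n,
    founders = sum(is.na(object$sire) & is.na(object$dam)),
    generations = max(object$generation),
    mean_f = mean(fac$f),
    max_f = max(fac$f),
    n_sires = length(unique(object$sire[!is.na(object$sire)])),
    n_dams = length(unique(object$dam[!is.na(object$dam)]))
  )
  class(out) <- "summary.pedigree"
  out
}

#' @method print summary.pedigree
#' @export
print.summary.pedigree <- function(x, ...) {
  cat("Pedigree of", x$n, "animals (", x$founders, "founders,",
      x$generations, "generations )\n")
  cat("  sires:", x$n_sires, " dams:", x$n_dams, "\n")
  cat(sprintf("  inbreeding: mean %.4f, max %.4f\n", x$mean_f, x$max_f))
  invisible(x)
}

#' Match external animal tokens to pedigree indices
#'
#' @param ped a [pedigree()] object.
#' @param ids character vector of animal tokens.
#' @return integer indices into the pedigree; unknown ids raise an error.
#' @export
ped_index <- function(ped, ids) {
  idx <- match(as.character(ids), ped$id)
  if (anyNA(idx))
    stop("unknown animal id(s): ",
         paste(utils::head(ids[is.na(idx)], 5L), collapse = ", "))
  idx
}
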