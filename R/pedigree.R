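#' Additive (numerator) relationship matrix from a pedigree
#'
#' Tabular method: founders (unknown parents) are unrelated and non-inbred
#' (A_ii = 1); for an individual k with parents s and d,
#' A_ki = (A_si + A_di) / 2 for earlier individuals i, and
#' A_kk = 1 + A_sd / 2 (the inbreeding coefficient is half the parents'
#' relationship). Entries are twice the coefficient of parentage. The
#' pedigree is topologically sorted first; a cycle is an error, and a parent
#' absent from the id column is treated as unknown (founder contribution).
#'
#' @param pedigree data.frame with columns id, parent1, parent2; "0", "",
#'   or NA mark unknown parents.
#' @return symmetric matrix with dimnames = ids (in topological order);
#'   diagonal in [1, 2].
#' @export
additive_relationship <- function(pedigree) {
  stopifnot(all(c("id", "parent1", "parent2") %in% names(pedigree)))
  ped <- data.frame(id = as.character(pedigree$id),
                    p1 = as.character(pedigree$parent1),
                    p2 = as.character(pedigree$parent2))
  unknown <- function(p) is.na(p) | p == "0" | p == ""
  ped$p1[unknown(ped$p1) | !(ped$p1 %in% ped$id)] <- NA
  ped$p2[unknown(ped$p2) | !(ped$p2 %in% ped$id)] <- NA
  if (anyDuplicated(ped$id)) stop("duplicated individual ids in pedigree")
  n <- nrow(ped)

  # Kahn topological sort; leftovers indicate a cycle
  order_ids <- character(0)
  placed <- character(0)
  remaining <- ped
  while (nrow(remaining) > 0) {
    ready <- (is.na(remaining$p1) | remaining$p1 %in% placed) &
             (is.na(remaining$p2) | remaining$p2 %in% placed)
    if (!any(ready)) stop("pedigree contains a cycle involving: ",
                          paste(remaining$id, collapse = ", "))
    order_ids <- c(order_ids, remaining$id[ready])
    placed <- order_ids
    remaining <- remaining[!ready, , drop = FALSE]
  }
  ped <- ped[match(order_ids, ped$id), ]

  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (k in seq_len(n)) {
    s <- ped$p1[k]; d <- ped$p2[k]
    if (k > 1) {
      prev <- seq_len(k - 1)
      as_ <- if (is.na(s)) rep(0, k - 1) else A[prev, s]
      ad_ <- if (is.na(d)) rep(0, k - 1) else A[prev, d]
      A[k, prev] <- A[prev, k] <- (as_ + ad_) / 2
    }
    A[k, k] <- 1 + (if (is.na(s) || is.na(d)) 0 else A[s, d] / 2)
  }
  A
}

#' Write / read a pedigree as 3-column CSV
#' @param pedigree data.frame(id, parent1, parent2); "0" = unknown.
#' @param path file path.
#' @return path (write) or the pedigree data.frame (read).
#' @export
write_pedigree_csv <- function(pedigree, path) {
  utils::write.csv(pedigree[, c("id", "parent1", "parent2")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_csv
#' @export
read_pedigree_csv <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  utils::read.csv(path, colClasses = "character")
}
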