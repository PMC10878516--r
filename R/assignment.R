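# Gated rectangular linear sum assignment on top of clue::solve_LSAP.
#
# Every matching step of the pipeline (frame-to-frame linking, daughter
# pairing, evaluation matching) is an optimal assignment under a cost with
# hard gates. solve_LSAP wants a non-negative, nrow <= ncol matrix with no
# notion of "forbidden", so forbidden pairs get a large sentinel cost and are
# stripped from the solution afterwards; the matrix is padded square with the
# sentinel so rows may remain unassigned.

.LSA_BIG <- 1e9

# cost: numeric matrix (may be non-square); forbid: logical matrix of the
# same shape (TRUE = pair not allowed). Returns data.frame(row, col) of the
# optimal allowed pairs.
solveAssignment <- function(cost, forbid = NULL) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0L || nc == 0L) return(data.frame(row = integer(), col = integer()))
  stopifnot(all(is.finite(cost[!(if (is.null(forbid)) matrix(FALSE, nr, nc) else forbid)])))
  m <- cost
  if (!is.null(forbid)) m[forbid] <- .LSA_BIG
  n <- max(nr, nc)
  pad <- matrix(.LSA_BIG, n, n)
  pad[seq_len(nr), seq_len(nc)] <- m
  sol <- clue::solve_LSAP(pad)
  row <- seq_len(nr)
  col <- as.integer(sol)[seq_len(nr)]
  keep <- col <= nc & pad[cbind(row, col)] < .LSA_BIG / 2
  data.frame(row = row[keep], col = col[keep])
}
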