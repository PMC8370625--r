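## Small dense two-phase simplex (Bland's rule, hence finite termination on
## degenerate problems) for the flux-balance LPs. The networks here have a
## dozen variables and a few dozen rows, so a dense tableau is ample.
## Interface mirrors what solveFBA needs: A1 x <= b1, A2 x >= b2,
## A3 x == b3, x >= 0.

.lpSolve <- function(a, A1 = NULL, b1 = NULL, A2 = NULL, b2 = NULL,
                     A3 = NULL, b3 = NULL, maximize = TRUE, tol = 1e-9) {
    n <- length(a)
    rows <- list()
    if (!is.null(A1) && length(b1))
        for (i in seq_along(b1)) rows[[length(rows) + 1L]] <-
            list(a = A1[i, ], b = b1[i], s = "<=")
    if (!is.null(A2) && length(b2))
        for (i in seq_along(b2)) rows[[length(rows) + 1L]] <-
            list(a = A2[i, ], b = b2[i], s = ">=")
    if (!is.null(A3) && length(b3))
        for (i in seq_along(b3)) rows[[length(rows) + 1L]] <-
            list(a = A3[i, ], b = b3[i], s = "==")
    m <- length(rows)
    if (m == 0L) stop("LP needs at least one constraint")

    ## normalise to b >= 0
    for (i in seq_len(m)) {
        if (rows[[i]]$b < 0) {
            rows[[i]]$a <- -rows[[i]]$a
            rows[[i]]$b <- -rows[[i]]$b
            rows[[i]]$s <- switch(rows[[i]]$s, "<=" = ">=", ">=" = "<=",
                                  "==" = "==")
        }
    }
    nSlack <- sum(vapply(rows, function(r) r$s != "==", logical(1)))
    nArt <- sum(vapply(rows, function(r) r$s != "<=", logical(1)))
    N <- n + nSlack + nArt
    T <- matrix(0, m, N + 1)
    basis <- integer(m)
    sIdx <- n; aIdx <- n + nSlack
    artCols <- integer(0)
    for (i in seq_len(m)) {
        T[i, seq_len(n)] <- rows[[i]]$a
        T[i, N + 1] <- rows[[i]]$b
        if (rows[[i]]$s == "<=") {
            sIdx <- sIdx + 1L; T[i, sIdx] <- 1; basis[i] <- sIdx
        } else if (rows[[i]]$s == ">=") {
            sIdx <- sIdx + 1L; T[i, sIdx] <- -1
            aIdx <- aIdx + 1L; T[i, aIdx] <- 1; basis[i] <- aIdx
            artCols <- c(artCols, aIdx)
        } else {
            aIdx <- aIdx + 1L; T[i, aIdx] <- 1; basis[i] <- aIdx
            artCols <- c(artCols, aIdx)
        }
    }

    pivot <- function(T, basis, pr, pc) {
        T[pr, ] <- T[pr, ] / T[pr, pc]
        for (i in seq_len(nrow(T))) {
            if (i != pr && abs(T[i, pc]) > 1e-14)
                T[i, ] <- T[i, ] - T[i, pc] * T[pr, ]
        }
        basis[pr] <- pc
        list(T = T, basis = basis)
    }

    ## minimise cost over current tableau with Bland's rule
    runSimplex <- function(T, basis, cost, active) {
        for (iter in seq_len(10000L)) {
            cb <- cost[basis]
            red <- cost[active] - as.vector(cb %*% T[, active, drop = FALSE])
            ent <- active[which(red < -tol)]
            if (!length(ent)) return(list(T = T, basis = basis, status = 0L))
            pc <- min(ent)                       # Bland: smallest index
            col <- T[, pc]
            pos <- which(col > tol)
            if (!length(pos)) return(list(T = T, basis = basis, status = 2L))
            ratio <- T[pos, N + 1] / col[pos]
            cand <- pos[ratio <= min(ratio) + 1e-12]
            pr <- cand[which.min(basis[cand])]   # Bland: smallest basis idx
            p <- pivot(T, basis, pr, pc)
            T <- p$T; basis <- p$basis
        }
        list(T = T, basis = basis, status = 3L)
    }

    active <- seq_len(N)
    if (nArt > 0) {
        c1 <- numeric(N); c1[artCols] <- 1
        r <- runSimplex(T, basis, c1, active)
        T <- r$T; basis <- r$basis
        phase1 <- sum(T[basis %in% artCols, N + 1])
        if (r$status != 0L || phase1 > 1e-7)
            return(list(solved = -1L, soln = rep(NA_real_, n),
                        value = NA_real_))
        ## drive zero-level artificials out of the basis where possible
        for (i in which(basis %in% artCols)) {
            nz <- setdiff(which(abs(T[i, seq_len(n + nSlack)]) > tol),
                          basis)
            if (length(nz)) {
                p <- pivot(T, basis, i, min(nz))
                T <- p$T; basis <- p$basis
            }
        }
        active <- setdiff(seq_len(N), artCols)
    }

    cost <- numeric(N)
    cost[seq_len(n)] <- if (maximize) -a else a
    r <- runSimplex(T, basis, cost, active)
    if (r$status == 2L)
        return(list(solved = -2L, soln = rep(NA_real_, n),
                    value = if (maximize) Inf else -Inf))
    if (r$status != 0L)
        return(list(solved = -1L, soln = rep(NA_real_, n), value = NA_real_))
    x <- numeric(N)
    x[r$basis] <- r$T[, N + 1]
    soln <- x[seq_len(n)]
    list(solved = 1L, soln = soln, value = sum(a * soln))
}
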