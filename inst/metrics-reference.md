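# Frozen metric conventions

This document fixes the exact formula conventions and tie rules used by
the nestedness and specialization metrics in this package. Tests assert
against these conventions; changing any of them is a breaking change.

Throughout, `W` is a non-negative grazers-by-ASVs weight matrix, `B` its
binarization (`B_ij = 1` iff `W_ij > 0`), `F_i` a row's fill (number of
positive cells), `M_i` a row's marginal total, and "sorted" means ordered
by decreasing marginal totals with ties broken by original index.

## NODF / NODF2

For an ordered row pair (i above j):

    term(i, j) = 100 * |{k : B_ik = B_jk = 1}| / F_j   if F_i > F_j and F_j > 0
               = 0                                      otherwise

Column pairs are treated symmetrically. NODF is the sum of all terms
divided by `nr*(nr-1)/2 + nc*(nc-1)/2`. The `as_is` variant evaluates the
matrix in the order given; `sorted` (the NODF2 dialect) first sorts rows
and columns by decreasing fill (ties by original index).

## Weighted NODF

Same pair condition on fills (strictly decreasing, `F_j > 0`); the term is

    100 * |{k : 0 < W_jk < W_ik}| / F_j

Strict inequality: matrices whose overlapping cells carry equal weights
score 0 on weighted terms. The `sorted` variant orders by decreasing fill
with marginal totals breaking fill ties (then original index).

## WNODA

No sorting requirement. For an unordered pair {a, b}, let i be the line
with the strictly larger marginal total and j the other; pairs with equal
totals contribute 0. The term is `100 * |{k : 0 < W_jk < W_ik}| / F_j`.
The statistic is the mean over all row pairs and column pairs.

Hand-worked 3x3 oracle frozen in tests:
`W = [[4,2,1],[2,3,0],[1,0,0]]` gives row terms (50, 100, 100) and column
terms (50, 100, 100), WNODA = 500/6 = 83.3333.

## WINE

Rows and columns sorted (decreasing totals, ties by index). Each filled
cell at sorted position (i, j) has corner distance
`d_ij = sqrt((i-1)^2 + (j-1)^2)`. Statistics:

- raw: `d_w = sum(W_ij * d_ij) / sum(W_ij)` over filled cells;
- `d_packed`: minimum attainable `d_w` (largest weights assigned to the
  smallest distances among the same number of cells);
- `d_random = mean(d_ij over all cells)` (uniform random placement);
- `eta = (d_random - d_w) / (d_random - d_packed)`, NA when
  `d_random = d_packed`.

Hand-worked 2x2 oracle: `W = [[4,2],[1,0]]` gives `d_w = 3/7`,
`d_packed = 3/7`, `d_random = (2 + sqrt(2))/4`, `eta = 1`.

## Matrix temperature

Cell (i, j) of an `nr x nc` matrix maps to the unit square at row
coordinate `r_i = (i - 0.5)/nr` and column coordinate `c_j = (j - 0.5)/nc`
(packed corner at the origin). The isocline of perfect nestedness for fill
`phi` is `f(x) = 1 - (1 - (1-x)^p)^(1/p)` with `p` solving
`integral_0^1 f = phi`. For each cell, the 45-degree diagonal through
`(r_i, c_j)` meets the isocline at row coordinate `x*` solving
`f(x) = x + (c_j - r_i)`; the signed normalized distance is
`u_ij = (r_i - x*) / (1 - |r_i - c_j|)`. A presence contributes
`max(u, 0)^2`, an absence `min(u, 0)^2`. The temperature is
`100 * sum(contributions) / (nr * nc) / 0.04145` evaluated at the
row/column permutation minimizing it, found by simulated annealing
(random pair swaps, geometric cooling, decreasing-fill warm start,
seeded; default budget 50000 proposals). A completely full matrix has
temperature 0 by convention.

## Discrepancy / discrepancy2

With columns in a fixed packing order, a row of fill `k` should occupy
the first `k` columns; every presence outside that block counts one
discrepancy. `fill_sorted` (the discrepancy2 dialect) orders columns by
decreasing totals, ties by original index; `fixed_order` uses the column
order given.

## H2 and H2'

Weights are integerized to total `K = 1000` by largest-remainder rounding.
`H2 = -sum p_ij ln p_ij` with `p = W_int / K`. `H2_max` (`H2_min`) is the
maximal (minimal) entropy over non-negative integer matrices with the
same marginals, found by greedy construction — proportional fill for the
maximum, largest-cell packing for the minimum — refined by
best-improvement 2x2 transfer moves with optimal integer step.
`H2' = (H2_max - H2) / (H2_max - H2_min)`, NA when the extremes coincide.
All three entropies use the integerized matrix, so
`H2_min <= H2 <= H2_max` always holds.

## d and d'

Row i's interaction distribution `p'_ij = W_ij / M_i` is compared with
partner availability `q_j = C_j / sum(W)` by Kullback-Leibler divergence
`d_i = sum p' ln(p'/q)`. Standardization: `d_max = ln(sum(W) / M_i)`;
`d_min` is the divergence of the largest-remainder integer allocation of
`round(M_i * K / sum(W))` units proportionally to `q`.
`d' = (d - d_min) / (d_max - d_min)`, clipped to [0, 1]; rows with no
interactions are NA.
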