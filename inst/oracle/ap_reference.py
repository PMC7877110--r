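"""Textbook affinity propagation in numpy, used as a cross-language
reference for the R implementation. Follows the canonical matrix-form
updates (responsibility, availability, damping, exemplar refinement)
without any perturbation of the input similarities.

Usage: python ap_reference.py S.tsv DAMPING MAX_ITER CONV_ITER
Prints the sorted 1-based exemplar indices, the per-sample 1-based
exemplar labels, and the number of sweeps run. The preference is taken
from the diagonal of S as given.
"""
import sys

import numpy as np


def main():
    S = np.loadtxt(sys.argv[1], delimiter="\t")
    damping = float(sys.argv[2])
    max_iter = int(sys.argv[3])
    conv = int(sys.argv[4])
    n = S.shape[0]
    ind = np.arange(n)
    A = np.zeros((n, n))
    R = np.zeros((n, n))
    E = np.zeros(n, dtype=bool)
    stable = 0
    for it in range(1, max_iter + 1):
        tmp = A + S
        I = np.argmax(tmp, axis=1)
        Y = tmp[ind, I]
        tmp[ind, I] = -np.inf
        Y2 = np.max(tmp, axis=1)
        Rnew = S - Y[:, None]
        Rnew[ind, I] = S[ind, I] - Y2
        R = damping * R + (1 - damping) * Rnew
        Rp = np.maximum(R, 0)
        Rp.flat[:: n + 1] = R.flat[:: n + 1]
        Anew = Rp.sum(axis=0) - Rp
        dA = np.diag(Anew).copy()
        Anew = np.minimum(Anew, 0)
        Anew.flat[:: n + 1] = dA
        A = damping * A + (1 - damping) * Anew
        Enew = (np.diag(A) + np.diag(R)) > 0
        stable = stable + 1 if np.array_equal(Enew, E) else 0
        E = Enew
        if stable >= conv and E.any():
            break
    I = np.flatnonzero(E)
    K = I.size
    if K == 0:
        print("")
        print("")
        print(it)
        return
    c = np.argmax(S[:, I], axis=1)
    c[I] = np.arange(K)
    for k in range(K):
        ii = np.where(c == k)[0]
        j = np.argmax(S[np.ix_(ii, ii)].sum(axis=0))
        I[k] = ii[j]
    c = np.argmax(S[:, I], axis=1)
    c[I] = np.arange(K)
    labels = I[c]
    print(",".join(str(i + 1) for i in np.sort(np.unique(labels))))
    print(",".join(str(l + 1) for l in labels))
    print(it)


if __name__ == "__main__":
    main()
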