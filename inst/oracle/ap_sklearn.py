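"""Independent affinity-propagation oracle (scikit-learn).

Usage: python ap_sklearn.py S.tsv DAMPING PREFERENCE MAX_ITER CONV_ITER
Reads a tab-separated similarity matrix and prints two lines: the sorted
1-based exemplar indices, and the 1-based exemplar index of every sample.
"""
import sys

import numpy as np
from sklearn.cluster import AffinityPropagation


def main():
    S = np.loadtxt(sys.argv[1], delimiter="\t")
    damping = float(sys.argv[2])
    pref = float(sys.argv[3])
    ap = AffinityPropagation(
        damping=damping,
        preference=pref,
        affinity="precomputed",
        max_iter=int(sys.argv[4]),
        convergence_iter=int(sys.argv[5]),
        random_state=0,
    ).fit(S)
    centers = ap.cluster_centers_indices_
    print(",".join(str(i + 1) for i in np.sort(centers)))
    print(",".join(str(centers[l] + 1) for l in ap.labels_))


if __name__ == "__main__":
    main()
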