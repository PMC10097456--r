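# Disease property set for soft-tissue sarcoma metastasis / local
# recurrence (group B).  Entry point: F0.
prop F0 = F1 \/ F10
prop F1 = (min X = <b3of3sphericity> <b1of3kurtosis> F2 \/ <-> X)
prop F2 = (min X = <b3of3sphericity> <b1of3kurtosis> F3 \/ <-> X)
prop F3 = (min X = <b3of3sphericity> <b1of3kurtosis> F4 \/ <- b3of3sphericity, b1of3kurtosis> X)
prop F4 = (min X = <b3of3sphericity> <b1of3kurtosis> tt \/ <- b3of3sphericity, b1of3kurtosis> X)
prop F10 = (min X = <b3of3sphericity> <b1of3kurtosis, b2of3kurtosis> <b3of3meshsurface, b3of3elongation> F11 \/ <-> X)
prop F11 = (min X = <b3of3sphericity> <b1of3kurtosis, b2of3kurtosis> <b3of3meshsurface, b2of3meshsurface> F12 \/ <-> X)
prop F12 = (min X = <b3of3sphericity> <b1of3kurtosis, b2of3kurtosis> <b3of3meshsurface, b3of3elongation> F13 \/ <-> X)
prop F13 = (min X = <b3of3sphericity> <b1of3kurtosis, b2of3kurtosis> <b3of3elongation, b3of3meshsurface> F14 \/ <-> X)
prop F14 = (min X = <b2of3meshsurface, b2of3elongation> [-] ff \/ <-> X)
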