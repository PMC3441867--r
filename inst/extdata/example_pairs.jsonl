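{"id":"e3","cause":[["I","other"],["broke up","verb"],["with","other"],["my","other"],["boyfriend","noun"]],"effect":[["life","noun"],["now","other"],["is","other"],["meaningless","verb"],["to","other"],["me","other"]],"label":"causality"}
{"id":"p02","cause":[["we","other"],["broke up","verb"],["my","other"],["boyfriend","noun"],["left","verb"]],"effect":[["my","other"],["life","noun"],["feels","other"],["meaningless","verb"]],"label":"causality"}
{"id":"p03","cause":[["broke up","verb"],["with","other"],["boyfriend","noun"],["yesterday","other"]],"effect":[["life","noun"],["seems","other"],["meaningless","verb"],["now","other"]],"label":"causality"}
{"id":"p04","cause":[["I","other"],["failed","verb"],["again","other"]],"effect":[["I","other"],["felt","other"],["upset","verb"]],"label":"causality"}
{"id":"p05","cause":[["exam","noun"],["failed","verb"]],"effect":[["very","other"],["upset","verb"],["feeling","noun"]],"label":"causality"}
{"id":"p06","cause":[["my","other"],["boss","noun"],["cut","verb"],["my","other"],["salary","noun"]],"effect":[["couldn't","other"],["sleep","verb"],["for","other"],["days","noun"]],"label":"causality"}
{"id":"p07","cause":[["boss","noun"],["cut","verb"],["the","other"],["salary","noun"]],"effect":[["no","other"],["sleep","verb"],["several","other"],["days","noun"]],"label":"causality"}
{"id":"p08","cause":[["friend","noun"],["argue","verb"]],"effect":[["lose","verb"],["energy","noun"]],"label":"causality"}
{"id":"p09","cause":[["parents","noun"],["divorce","verb"]],"effect":[["family","noun"],["break","verb"]],"label":"causality"}
{"id":"p10","cause":[["investment","noun"],["setback","noun"]],"effect":[["life","noun"],["trouble","noun"]],"label":"causality"}
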