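{"id":"e1","tokens":[["I","other"],["couldn't","other"],["sleep","verb"],["for","other"],["several","other"],["days","noun"],["because","other"],["my","other"],["boss","noun"],["cut","verb"],["my","other"],["salary","noun"]]}
{"id":"f1b","tokens":[["I","other"],["broke up","verb"],["with","other"],["my","other"],["boyfriend","noun"],["so","other"],["life","noun"],["now","other"],["is","other"],["meaningless","verb"],["to","other"],["me","other"]]}
{"id":"plain","tokens":[["I","other"],["failed","verb"],["again","other"]]}
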