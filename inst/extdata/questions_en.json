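{
  "note": "question phrasings for log readability only; the simulators operate on the symbolic scenario",
  "order_0": "Where is the chocolate now?",
  "order_1": "Where will Murat look for the chocolate?",
  "order_2": "Where does Ayla think that Murat will look for the chocolate?",
  "feedback_correct": "Correct",
  "feedback_wrong": "Wrong"
}
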