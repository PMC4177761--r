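enzyme	Bacteria	Archaea	Eukarya
5.4.2.2	widely	widely	widely
5.4.2.7	partially	absent	absent
2.7.6.1	widely	widely	widely
2.4.2.14	widely	widely	widely
6.3.4.13	widely	widely	widely
2.1.2.2	widely	widely	widely
6.3.5.3	widely	widely	widely
6.3.3.1	widely	widely	widely
6.3.4.18	widely	widely	widely
5.4.99.18	widely	widely	partially
4.1.1.21	absent	absent	widely
6.3.2.6	widely	widely	widely
4.3.2.2	widely	widely	widely
2.1.2.3	widely	partially	widely
3.5.4.10	widely	partially	widely
6.3.4.23	absent	partially	absent
2.4.2.8	widely	widely	widely
2.4.2.7	widely	sparsely	widely
6.3.4.4	widely	widely	widely
2.7.4.3	widely	widely	widely
2.7.4.6	widely	widely	widely
2.7.1.40	widely	widely	widely
1.17.4.1	widely	widely	widely
1.17.4.2	partially	partially	absent
1.1.1.205	widely	widely	widely
6.3.5.2	widely	widely	widely
2.7.4.8	widely	absent	widely
6.3.5.5	widely	widely	widely
2.1.3.2	widely	widely	widely
3.5.2.3	widely	widely	widely
1.3.1.14	partially	widely	sparsely
1.3.5.2	partially	absent	widely
1.3.98.1	partially	sparsely	sparsely
2.4.2.10	widely	widely	widely
4.1.1.23	widely	widely	widely
2.7.4.14	widely	widely	widely
2.7.4.22	widely	widely	widely
6.3.4.2	widely	widely	widely
1.8.1.9	widely	widely	widely
3.6.1.19	widely	widely	widely
3.6.1.23	widely	widely	widely
3.5.4.12	widely	widely	widely
3.5.4.13	partially	partially	absent
2.1.1.45	partially	sparsely	widely
2.1.1.148	partially	partially	absent
2.7.1.48	widely	sparsely	widely
2.4.2.3	sparsely	sparsely	sparsely
3.5.4.5	widely	sparsely	widely
2.4.2.2	partially	absent	absent
2.4.2.9	widely	widely	widely
2.7.1.74	absent	absent	sparsely
2.7.1.21	partially	sparsely	sparsely
2.4.2.4	sparsely	sparsely	sparsely
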