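49492a00080000000f000001040001000000800000000101040001000000800000000201030001000000080000000301030001000000050000000601030001000000010000000e01020016000000c20000001101040001000000100100001501030001000000010000001601040001000000800000001701040001000000b80200001a01050001000000e80000001b01050001000000f0000000280103000100000001000000310102000c000000f80000003d0103000100000002000000000000007b227368617065223a205b3132382c203132385d7d0000000000000000000000000000000000010000000100000001000000010000007469666666696c652e707900000000000000000000000000800000703824160d0784426150b864360c0887446240303c4e2d178c43221198e410391d904861f229200c7f2594422372996410e12d894ae613386abe45329a4e6153887006753f85cf27e5ca04468545943162d47a44e6991320d36334fa94398d4baad22a9112f566135baf45809619d5825ab39059ac91db5414eb59b6dae2e45b946aeb1311ddea77a8203ef937b5826ff24b8ca42383b65c84f88a3620978c01e16ea7da6e4b2107882f6f797b4c74219c8be5a506cb268b20d686e9b39aa8494f07acb2366eda0cdcb0e55ed862033b4876e644c989efb11b94659779b582176f5c2b08f379cc9a0a78f23c4093a798c18b7af03e84a089abeb9a6d7ddb22725be4bbd51bb3bedf066631edfa2488ee37b77b087cfcae5fa841deaafe3ecd04008413098406dc2162036903a4478a09062a50616acec02d9a2e43a8108422828cefdc2a838aad7c2a28b87008b6be434968e70443e849330345aa0a1666a6318abe940291b322ba8c8bac5299984d0c749524219baf1fa2656b0121ba889074e3c908b1a0c6c9907a523cbff2ac1e183e2cb9e12b4b4ee28a61c8530c7690148944a29facc49a6935bea83920a74cd33a0c4dbcf3aaa85a42930b246dc65333c80ac75382062c2ff4324054a4b454608901b2acd63d437411eb3b4b508106a2d1d478060fc5b4e806624cb4ca443e52b53085013a60b50aba9e731504a41c7225669a1c31bd6e981da82d449640606524b206923b38353c72615d25cfc8b00b66ab232c3d1d1a6fbda0940a9114026f3d95da583dd534c84d00d7e819b540dae9494294dcb3521c3b2e1330b31445a2532176a1a24b2f7c2162b5130f8e3164aa4d53d61a1668dad74a440dc634e8dcb0df88e99f2a614900875638e6023188a42d50a112bec74c9b532744aa678e4fa8389ec66508482f1b51c743b18aa5a6646b6f2405f391263559d6379c22f9b62992244808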